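# Hyperpolarizing pulse (0.5 nA) followed by a depolarizing pulse (0.2 nA,
# the magnitude of the published post-stimulation-recovery protocol)
segments:
  - {duration_ms: 5000,  i_app_nA: 0.0,  condition: "N"}
  - {duration_ms: 2000,  i_app_nA: -0.5, condition: "N"}
  - {duration_ms: 5000,  i_app_nA: 0.2,  condition: "N"}
  - {duration_ms: 12000, i_app_nA: 0.0,  condition: "N"}
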