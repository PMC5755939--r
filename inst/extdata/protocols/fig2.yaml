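# Depolarizing current pulse under normocapnia (0.1 nA, 5 s)
segments:
  - {duration_ms: 5000, i_app_nA: 0.0, condition: "N"}
  - {duration_ms: 5000, i_app_nA: 0.1, condition: "N"}
  - {duration_ms: 5000, i_app_nA: 0.0, condition: "N"}
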