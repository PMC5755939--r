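# Normocapnia, constant
segments:
  - {duration_ms: 10000, i_app_nA: 0.0, condition: [5, 7.45, 7.23]}
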