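# Hypocapnic alkalosis, constant
segments:
  - {duration_ms: 10000, i_app_nA: 0.0, condition: [2.5, 7.55, 7.30]}
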