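# Sensitivity conditions in sequence (no applied current)
segments:
  - {duration_ms: 5000, i_app_nA: 0.0, condition: "N"}
  - {duration_ms: 5000, i_app_nA: 0.0, condition: "IH"}
  - {duration_ms: 5000, i_app_nA: 0.0, condition: "IA"}
  - {duration_ms: 5000, i_app_nA: 0.0, condition: "HA"}
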