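# Chemical step: normocapnia -> hypercapnic acidosis (5% -> 15% CO2) -> back
segments:
  - {duration_ms: 5000, i_app_nA: 0.0, condition: "N"}
  - {duration_ms: 5000, i_app_nA: 0.0, condition: "HA"}
  - {duration_ms: 5000, i_app_nA: 0.0, condition: "N"}
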