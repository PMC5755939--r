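cell:
  c: 0.04
  R_in: 241.5
  V_r: -60.0
  A: 4.0
  g_task: 0.002
  ZFRT: 0.0394
reversal:
  E_K: -93.0
  E_Na: 45.0
  E_Ca: 60.0
  E_H: -45.0
  E_Cl: -93.0
channels:
  Na:
    name: Na
    kind: standard
    gbar: 0.594
    E_rev: 45.0
    activation:
      V_half: -34.77
      k: 10.5
      a: 0.05
      b: 0.15
      V_tau: -43.0
      k_tau: 10.5
      tau_form: gaussian
      exponent: 3
    inactivation:
      V_half: -50.3
      k: -6.5
      a: 0.5
      b: 7.5
      V_tau: -43.0
      k_tau: 6.5
      tau_form: gaussian
      exponent: 1
    inact_exponent: 1
    chemo: ~
    provenance: table
  Kdr:
    name: Kdr
    kind: standard
    gbar: 0.0384
    E_rev: -93.0
    activation:
      V_half: -15.0
      k: 7.0
      a: 1.0
      b: 4.0
      V_tau: -20.0
      k_tau: 7.0
      tau_form: reciprocal_cosh
      exponent: 1
    inactivation: ~
    inact_exponent: 0
    chemo:
      w_pHi: 1.0
      w_pHo: 0.0
      w_CO2: 0.0
      pK_i: 7.1
      pK_o: .na.real
      co2_half: .na.real
      h_i: 15.0
      h_o: .na.real
      h_c: .na.real
    provenance: table
  KM:
    name: KM
    kind: standard
    gbar: 0.0005
    E_rev: -93.0
    activation:
      V_half: -30.0
      k: 9.0
      a: 100.0
      b: 0.0
      V_tau: .na
      k_tau: 9.0
      tau_form: reciprocal_cosh
      exponent: 1
    inactivation: ~
    inact_exponent: 0
    chemo: ~
    provenance: table
  KA:
    name: KA
    kind: standard
    gbar: 1.5
    E_rev: -93.0
    activation:
      V_half: -57.0
      k: 8.5
      a: 0.37
      b: 2.0
      V_tau: -55.0
      k_tau: 8.5
      tau_form: reciprocal_cosh
      exponent: 4
    inactivation:
      V_half: -78.0
      k: -6.0
      a: 19.0
      b: 45.0
      V_tau: -80.0
      k_tau: 6.0
      tau_form: reciprocal_cosh
      exponent: 1
    inact_exponent: 1
    chemo:
      w_pHi: 0.3
      w_pHo: 0.7
      w_CO2: 0.0
      pK_i: 7.4
      pK_o: 7.3
      co2_half: .na.real
      h_i: 15.0
      h_o: 15.0
      h_c: .na.real
    provenance: table
  CaT:
    name: CaT
    kind: standard
    gbar: 0.1126
    E_rev: 60.0
    activation:
      V_half: -54.15
      k: 6.2
      a: 0.7
      b: 13.5
      V_tau: -76.0
      k_tau: 6.2
      tau_form: reciprocal_cosh
      exponent: 2
    inactivation:
      V_half: -81.0
      k: -4.0
      a: 28.0
      b: 300.0
      V_tau: -81.0
      k_tau: 4.0
      tau_form: gaussian
      exponent: 1
    inact_exponent: 1
    chemo:
      w_pHi: 0.0
      w_pHo: 1.0
      w_CO2: 0.0
      pK_i: .na.real
      pK_o: 6.9
      co2_half: .na.real
      h_i: .na.real
      h_o: 1.0
      h_c: .na.real
    provenance: table
  CaL:
    name: CaL
    kind: standard
    gbar: 0.0005
    E_rev: 60.0
    activation:
      V_half: -20.0
      k: 8.4
      a: 0.5
      b: 1.5
      V_tau: -20.0
      k_tau: 8.4
      tau_form: reciprocal_cosh
      exponent: 2
    inactivation: ~
    inact_exponent: 0
    chemo:
      w_pHi: 0.0
      w_pHo: 0.3
      w_CO2: 0.7
      pK_i: .na.real
      pK_o: 6.5
      co2_half: 5.0
      h_i: .na.real
      h_o: 1.0
      h_c: 5.0
    provenance: table
  CaN:
    name: CaN
    kind: standard
    gbar: 0.0005
    E_rev: 60.0
    activation:
      V_half: -10.0
      k: 7.0
      a: 1.0
      b: 1.5
      V_tau: -15.0
      k_tau: 7.0
      tau_form: reciprocal_cosh
      exponent: 2
    inactivation: ~
    inact_exponent: 0
    chemo: ~
    provenance: default-decision
  H:
    name: H
    kind: standard
    gbar: 0.018
    E_rev: -45.0
    activation:
      V_half: -80.0
      k: -5.0
      a: 900.0
      b: 0.0
      V_tau: -80.0
      k_tau: 5.0
      tau_form: reciprocal_cosh
      exponent: 1
    inactivation: ~
    inact_exponent: 0
    chemo: ~
    provenance: default-decision
  Kir:
    name: Kir
    kind: kir
    gbar: 0.002
    E_rev: -93.0
    activation: ~
    inactivation: ~
    inact_exponent: 0
    chemo:
      w_pHi: 1.0
      w_pHo: 0.0
      w_CO2: 0.0
      pK_i: 7.0
      pK_o: .na.real
      co2_half: .na.real
      h_i: 15.0
      h_o: .na.real
      h_c: .na.real
    provenance: calibrated
  BK:
    name: BK
    kind: bk
    gbar: 0.2
    E_rev: -93.0
    activation: ~
    inactivation: ~
    inact_exponent: 0
    chemo:
      w_pHi: 1.0
      w_pHo: 0.0
      w_CO2: 0.0
      pK_i: 6.5
      pK_o: .na.real
      co2_half: .na.real
      h_i: 2.0
      h_o: .na.real
      h_c: .na.real
    provenance: calibrated
  SK:
    name: SK
    kind: sk
    gbar: 0.003
    E_rev: -93.0
    activation: ~
    inactivation: ~
    inact_exponent: 0
    chemo: ~
    provenance: table
  TASK:
    name: TASK
    kind: leak_component
    gbar: 0.002
    E_rev: -93.0
    activation: ~
    inactivation: ~
    inact_exponent: 0
    chemo:
      w_pHi: 0.5
      w_pHo: 0.5
      w_CO2: 0.0
      pK_i: 7.3
      pK_o: 7.4
      co2_half: .na.real
      h_i: 1.0
      h_o: 1.0
      h_c: .na.real
    provenance: table
calcium:
  CSF: 0.201
  F: 96500.0
  d: 0.062
  K_s: 4.0e-08
  K_m: 0.0001
  B_tot: 0.03
  K_d: 0.001
  'n': 2.0
  K_c: 3.0e-08
  sk_tau_a: 5.0
  Ca0: 0.002
options:
  ph_hill_form: protonation
  bk_couples_to: CaN
  spike_threshold: -20.0
  dvdt_threshold: 10.0
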