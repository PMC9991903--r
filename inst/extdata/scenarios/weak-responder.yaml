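# A weakly responding subject: lower actuator coupling, higher preserved
# baseline, and an active CO2 chemoreflex (drive amplitude and respiratory
# rate rise with PaCO2 above the set point, first-order smoothed).
scenario: weak-responder
schema_version: 1
duration: 90
sim:
  R_aw: 2.5
  C_L: 63.5
  C_cw: 120.0
  V_D: 60.0
  body_mass: 38.0
  f_di: 0.7
  severed_phrenic: false
  A0: 1.2
  G_drive: 0.08
  paco2_set: 42.0
  rr_base: 20.0
  G_rr: 0.25
  Ti_frac: 0.16
  tau_rel: 0.25
  tau_drive: 20.0
  k_act: 0.08
  beta_eso: 0.72
  gamma_ab: 0.6
  k_disp: 0.331
  lambda_disp: 1.6
  tau_act: 0.03
  paco2_0: 48.0
  hco3: 24.0
  vco2: 150.0
  v_store: 15.0
  noise:
    flow: 0.005
    p_pl: 0.08
    p_ab: 0.015
    p_act: 0.05
    d_dia: 0.01
    amp: 0.03
  seed: 4102
controller:
  mode: synchronized
  threshold: 0.04
  hysteresis: 0.03
  waveform:
    peak: 20.0
    t_rise: 0.25
    t_hold: 0.35
    t_release: 0.3
    shape: trapezoid
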