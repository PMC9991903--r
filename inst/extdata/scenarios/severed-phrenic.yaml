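# Bilateral phrenicotomy under isoflurane: the diaphragmatic component of
# the muscle pressure is zeroed and only a weak, slow, irregular ribcage
# effort remains (35% breath-amplitude jitter). Used with independent
# actuation (rate incommensurate with the residual rhythm) for the
# timing-alignment regressions.
scenario: severed-phrenic
schema_version: 1
duration: 720
sim:
  R_aw: 2.5
  C_L: 63.5
  C_cw: 120.0
  V_D: 60.0
  body_mass: 35.0
  f_di: 0.8
  severed_phrenic: true
  A0: 1.8
  G_drive: 0.0
  paco2_set: 40.0
  rr_base: 15.5
  G_rr: 0.0
  Ti_frac: 0.45
  tau_rel: 0.4
  tau_drive: 20.0
  k_act: 0.149
  beta_eso: 0.72
  gamma_ab: 0.6
  k_disp: 0.331
  lambda_disp: 1.6
  tau_act: 0.03
  paco2_0: 55.0
  hco3: 24.0
  vco2: 150.0
  v_store: 15.0
  noise:
    flow: 0.005
    p_pl: 0.08
    p_ab: 0.015
    p_act: 0.05
    d_dia: 0.01
    amp: 0.35
  seed: 4103
controller:
  mode: independent
  threshold: 0.04
  hysteresis: 0.03
  rate: 18.0
  waveform:
    peak: 20.0
    t_rise: 0.25
    t_hold: 0.35
    t_release: 1.2
    shape: trapezoid
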