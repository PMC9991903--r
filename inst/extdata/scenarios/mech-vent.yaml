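# Passive subject on positive-pressure mechanical ventilation; muscle drive
# off. Source of the passive chest-wall compliance line for the Campbell
# diagram.
scenario: mech-vent
schema_version: 1
duration: 60
sim:
  R_aw: 2.5
  C_L: 63.5
  C_cw: 120.0
  V_D: 60.0
  body_mass: 35.0
  f_di: 0.7
  severed_phrenic: false
  A0: 0.0
  G_drive: 0.0
  paco2_set: 40.0
  rr_base: 18.0
  G_rr: 0.0
  Ti_frac: 0.3
  tau_rel: 0.25
  tau_drive: 20.0
  k_act: 0.149
  beta_eso: 0.72
  gamma_ab: 0.6
  k_disp: 0.331
  lambda_disp: 1.6
  tau_act: 0.03
  paco2_0: 40.0
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
  seed: 4104
controller:
  mode: "off"
ventilator:
  peak: 9.0
  rate: 18.0
  ti_frac: 0.35
  t_ramp: 0.15
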