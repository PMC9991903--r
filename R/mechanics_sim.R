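#' Respiratory muscle pressure profile
#'
#' Occupational waveform of one inspiratory effort: a smooth rising limb
#' over the inspiratory time `Ti` followed by exponential relaxation,
#'
#'   P(phase) = A * sin(pi * phase / (2 Ti))^2        for phase <= Ti
#'   P(phase) = A * exp(-(phase - Ti) / tau_rel)      for phase  > Ti
#'
#' Zero at onset, maximum `A` at `phase = Ti`, monotone non-increasing
#' afterwards, tending to zero. Vectorized over `phase`.
#'
#' @param phase seconds into the breath, >= 0.
#' @param amplitude peak muscle pressure `A`, cmH2O.
#' @param Ti inspiratory rise time, s, > 0.
#' @param tau_rel relaxation time constant, s, > 0.
#' @return muscle pressure, cmH2O.
#' @export
muscle_pressure <- function(phase, amplitude, Ti, tau_rel) {
  if (Ti <= 0) stop("Ti must be > 0")
  if (tau_rel <= 0) stop("tau_rel must be > 0")
  if (any(phase < 0)) stop("phase must be >= 0")
  ifelse(phase <= Ti,
         amplitude * sin(pi * phase / (2 * Ti))^2,
         amplitude * exp(-(phase - Ti) / tau_rel))
}

#' Simulator configuration
#'
#' Mechanical and chemoreflex parameters of the surrogate subject: a
#' single-compartment equation of motion
#'
#'   R_aw * Q + V / C_rs = P_vent + P_mus_di + P_mus_rc + P_act_eq,
#'   1 / C_rs = 1 / C_L + 1 / C_cw,
#'
#' with the muscle pressure split into a diaphragmatic fraction `f_di` and a
#' ribcage remainder, an additive actuator coupling `P_act_eq = k_act *
#' p_act`, and a CO2 chemoreflex that scales drive amplitude and respiratory
#' rate with PaCO2 above a set point (first-order smoothed). Severing the
#' phrenic nerves zeroes the diaphragmatic component only.
#'
#' Sensor channels are derived as
#'   P_pl  = V / C_cw - (P_mus_di + P_mus_rc + (1 - beta_eso) * P_act_eq)
#'   P_ab  = gamma_ab * (P_mus_di + P_act_eq)
#'   d_dia = k_disp * (P_mus_di + lambda_disp * P_act_eq)
#' where `lambda_disp` >= 1 weights the actuator term in the displacement
#' channel (M-mode displacement is read along the actuator line, where the
#' PAM's local push exceeds its volume-averaged effect -- the actuators act
#' along two discrete lines on the diaphragm), and `beta_eso` is the fraction of the actuator's equivalent pressure
#' transmitted mechanically to the oesophageal balloon (the implanted PAM
#' sits against the mediastinum, so part of its push registers directly on
#' the pleural-surrogate sensor rather than through the pleural space).
#'
#' @param R_aw airway resistance, cmH2O s/l.
#' @param C_L lung compliance, ml/cmH2O.
#' @param C_cw chest-wall compliance, ml/cmH2O.
#' @param V_D series dead space, ml.
#' @param body_mass kg.
#' @param f_di diaphragm fraction of total muscle pressure, in [0, 1].
#' @param severed_phrenic if TRUE the diaphragmatic muscle component is
#'   zeroed (bilateral phrenicotomy model); the ribcage component remains.
#' @param A0 baseline muscle-pressure amplitude, cmH2O.
#' @param G_drive chemoreflex amplitude gain, cmH2O per mmHg above set point.
#' @param paco2_set chemoreflex set point, mmHg.
#' @param rr_base baseline respiratory rate, breaths/min.
#' @param G_rr chemoreflex rate gain, breaths/min per mmHg above set point.
#' @param Ti_frac inspiratory fraction of the breath period, in (0, 1).
#' @param tau_rel muscle relaxation time constant, s.
#' @param tau_drive chemoreflex smoothing time constant, s.
#' @param k_act actuator coupling gain, cmH2O per psi.
#' @param beta_eso fraction of actuator pressure transmitted directly to the
#'   oesophageal sensor, in [0, 1).
#' @param gamma_ab abdominal transmission coefficient.
#' @param k_disp diaphragm displacement gain, cm per cmH2O.
#' @param lambda_disp local actuator weighting of the displacement channel.
#' @param tau_act electropneumatic lag time constant, s.
#' @param paco2_0 initial PaCO2, mmHg.
#' @param hco3 bicarbonate, mmol/l (held constant).
#' @param vco2 metabolic CO2 production, ml/min.
#' @param v_store effective CO2 storage volume, l.
#' @param noise list of per-channel Gaussian noise SDs (`flow` l/s, `p_pl`,
#'   `p_ab` cmH2O, `p_act` psi, `d_dia` cm) and breath-amplitude jitter SD
#'   (`amp`, multiplicative fraction).
#' @param seed RNG seed for all simulator randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(R_aw = 4, C_L = 60, C_cw = 120, V_D = 60,
                       body_mass = 35, f_di = 0.7, severed_phrenic = FALSE,
                       A0 = 2.5, G_drive = 0, paco2_set = 40,
                       rr_base = 19.3, G_rr = 0, Ti_frac = 0.3,
                       tau_rel = 0.25, tau_drive = 20,
                       k_act = 0.5, beta_eso = 0, gamma_ab = 0.6,
                       k_disp = 0.2, lambda_disp = 1, tau_act = 0.08,
                       paco2_0 = 45, hco3 = 24, vco2 = 150, v_store = 15,
                       noise = list(flow = 0.005, p_pl = 0.08, p_ab = 0.015,
                                    p_act = 0.05, d_dia = 0.01, amp = 0.03),
                       seed = 1L) {
  cfg <- list(R_aw = R_aw, C_L = C_L, C_cw = C_cw, V_D = V_D,
              body_mass = body_mass, f_di = f_di,
              severed_phrenic = isTRUE(severed_phrenic),
              A0 = A0, G_drive = G_drive, paco2_set = paco2_set,
              rr_base = rr_base, G_rr = G_rr, Ti_frac = Ti_frac,
              tau_rel = tau_rel, tau_drive = tau_drive,
              k_act = k_act, beta_eso = beta_eso, gamma_ab = gamma_ab,
              k_disp = k_disp, lambda_disp = lambda_disp, tau_act = tau_act,
              paco2_0 = paco2_0, hco3 = hco3, vco2 = vco2, v_store = v_store,
              noise = noise, seed = as.integer(seed))
  num <- cfg[!(names(cfg) %in% c("noise", "severed_phrenic"))]
  if (any(!vapply(num, function(x) all(is.finite(x)), logical(1))))
    stop("non-finite value in simulator parameters")
  if (any(!vapply(noise, is.finite, logical(1))) || any(unlist(noise) < 0))
    stop("noise SDs must be finite and >= 0")
  stopifnot(R_aw > 0, C_L > 0, C_cw > 0, V_D >= 0, body_mass > 0,
            f_di >= 0, f_di <= 1, A0 >= 0, G_drive >= 0, rr_base > 0,
            G_rr >= 0, Ti_frac > 0, Ti_frac < 1, tau_rel > 0,
            tau_drive > 0, k_act >= 0, beta_eso >= 0, beta_eso < 1,
            gamma_ab >= 0, k_disp >= 0, lambda_disp >= 0, tau_act > 0, paco2_0 > 0,
            hco3 > 0, vco2 > 0, v_store > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Positive-pressure ventilator settings
#'
#' Pressure-control mechanical ventilation: a trapezoidal airway-pressure
#' cycle at a fixed rate. The subject is assumed passive (muscle drive off).
#'
#' @param peak inspiratory pressure above PEEP-reference, cmH2O.
#' @param rate breaths/min.
#' @param ti_frac inspiratory fraction of the cycle.
#' @param t_ramp rise/release ramp, s.
#' @return list of class `ventilator_settings`.
#' @export
ventilator_settings <- function(peak = 10, rate = 18, ti_frac = 0.35,
                                t_ramp = 0.15) {
  stopifnot(peak > 0, rate > 0, ti_frac > 0, ti_frac < 1, t_ramp >= 0)
  structure(list(peak = peak, rate = rate, ti_frac = ti_frac,
                 t_ramp = t_ramp), class = "ventilator_settings")
}

#' Simulate the surrogate subject
#'
#' Integrates the single-compartment equation of motion at the output rate
#' (1 kHz, Heun's method; the electropneumatic lag is advanced by its exact
#' exponential update) under one of three drives: spontaneous/assisted
#' breathing (muscle drive, optionally with actuator assist), or passive
#' positive-pressure mechanical ventilation. The CO2 balance is advanced
#' every step from the running alveolar-ventilation estimate and feeds back
#' on drive amplitude and rate through the chemoreflex gains.
#'
#' Flow-triggered actuation uses exactly the causal state machine of
#' [detect_triggers()] applied to the noisy flow channel as it is produced,
#' so offline detection on the emitted record reproduces the online trigger
#' times.
#'
#' @param config a [sim_config()].
#' @param controller a [controller_config()] or NULL (off).
#' @param ventilator a [ventilator_settings()] or NULL. Mutually exclusive
#'   with an active muscle drive: supply `A0 = 0` when ventilating.
#' @param duration record duration, s; at least one breath period.
#' @param fs sampling rate, Hz (all channels).
#' @param scenario scenario name stored in record metadata.
#' @return list with elements `record` (a [waveform_record()]), `triggers`
#'   (data.frame of actuation triggers), `gas` (1 Hz data.frame of `t`,
#'   `paco2`, `hco3`, `ph`) and `breaths_gt` (per-breath ground truth:
#'   `t_start`, `amplitude`, `Ti`, `period`, `tv_ml`).
#' @export
simulate_subject <- function(config, controller = NULL, ventilator = NULL,
                             duration = 60, fs = 1000,
                             scenario = "custom") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(controller)) stopifnot(inherits(controller, "controller_config"))
  if (!is.null(ventilator)) stopifnot(inherits(ventilator, "ventilator_settings"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  base_period <- if (is.null(ventilator)) 60 / config$rr_base
                 else 60 / ventilator$rate
  if (duration < base_period)
    stop("duration must cover at least one breath period (",
         sprintf("%.2f", base_period), " s)")
  if (!is.null(ventilator) && config$A0 > 0)
    stop("exactly one drive may be active: set A0 = 0 under mechanical ",
         "ventilation")

  # restore the caller's RNG state on exit; all randomness from config$seed
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(config$seed)

  n <- as.integer(round(duration * fs))
  dt <- 1 / fs
  C_rs <- 1 / (1 / config$C_L + 1 / config$C_cw)  # ml/cmH2O
  di_scale <- if (config$severed_phrenic) 0 else 1

  ns <- config$noise
  e_flow <- rnorm(n, 0, ns$flow)
  e_ppl <- rnorm(n, 0, ns$p_pl)
  e_pab <- rnorm(n, 0, ns$p_ab)
  e_pact <- rnorm(n, 0, ns$p_act)
  e_ddia <- rnorm(n, 0, ns$d_dia)
  max_breaths <- ceiling(duration / 60 *
                           (config$rr_base + config$G_rr * 120)) + 10L
  jit <- rnorm(max_breaths, 0, ns$amp)

  mode <- if (is.null(controller)) "off" else controller$mode
  wf <- if (is.null(controller)) NULL else controller$waveform
  thr <- if (mode == "synchronized") controller$threshold else NA_real_
  rearm_level <- if (mode == "synchronized") thr * (1 - controller$hysteresis)
                 else NA_real_
  refr <- if (is.null(controller)) 0 else controller$refractory
  sched <- if (mode == "independent")
    independent_schedule(controller$rate, duration)$t_trigger else numeric(0)
  sched_i <- 1L

  # outputs
  flow_o <- numeric(n); ppl_o <- numeric(n); pab_o <- numeric(n)
  pact_o <- numeric(n); ddia_o <- numeric(n)
  trig_t <- numeric(0); trig_cause <- character(0)
  gb_t <- numeric(0); gb_amp <- numeric(0); gb_Ti <- numeric(0)
  gb_per <- numeric(0); gb_tv <- numeric(0)
  n_gas <- floor(duration) + 1L
  gas_t <- numeric(n_gas); gas_paco2 <- numeric(n_gas); gas_k <- 0L

  # state
  V <- 0           # ml above reference
  p_act <- 0       # psi
  paco2 <- config$paco2_0
  A_eff <- config$A0 + config$G_drive * max(paco2 - config$paco2_set, 0)
  RR_eff <- config$rr_base + config$G_rr * max(paco2 - config$paco2_set, 0)
  spont <- is.null(ventilator) && (config$A0 > 0 || config$G_drive > 0)
  # steady-state-consistent initial VA estimate; zero under apnoea
  va <- if (spont || !is.null(ventilator)) 0.863 * config$vco2 / paco2 else 0
  armed <- TRUE
  last_fire <- -Inf
  t_trig_active <- -Inf
  breath_t0 <- -Inf; breath_amp <- 0; breath_Ti <- 1; breath_per <- base_period
  next_breath <- 0; breath_idx <- 0L
  breath_vmax <- 0; breath_v0 <- 0
  vent_per <- if (is.null(ventilator)) Inf else 60 / ventilator$rate
  vent_ti <- if (is.null(ventilator)) 0 else ventilator$ti_frac * vent_per
  lag_fac <- 1 - exp(-dt / config$tau_act)
  k_gas <- (0.863 * config$vco2) / config$v_store / 60   # mmHg per s term
  cyc_len <- if (is.null(wf)) 0 else waveform_cycle_length(wf)

  p_mus_at <- function(t) {
    ph <- t - breath_t0
    if (!spont || ph < 0 || ph > breath_per) return(0)
    if (ph <= breath_Ti)
      breath_amp * sin(pi * ph / (2 * breath_Ti))^2
    else
      breath_amp * exp(-(ph - breath_Ti) / config$tau_rel)
  }
  p_vent_at <- function(t) {
    if (is.null(ventilator)) return(0)
    tc <- t %% vent_per
    rmp <- ventilator$t_ramp
    if (tc < rmp) ventilator$peak * tc / max(rmp, 1e-9)
    else if (tc < vent_ti) ventilator$peak
    else if (tc < vent_ti + rmp) ventilator$peak * (1 - (tc - vent_ti) / rmp)
    else 0
  }
  p_cmd_at <- function(t) {
    ts <- t - t_trig_active
    if (is.null(wf) || ts < 0 || ts >= cyc_len) return(0)
    if (wf$shape == "raised-cosine")
      return(wf$peak * 0.5 * (1 - cos(2 * pi * ts / cyc_len)))
    if (ts < wf$t_rise) wf$peak * ts / wf$t_rise
    else if (ts < wf$t_rise + wf$t_hold) wf$peak
    else wf$peak * (cyc_len - ts) / wf$t_release
  }

  for (i in seq_len(n)) {
    t <- (i - 1L) * dt

    # breath clock (spontaneous/assisted drive)
    if (spont && t >= next_breath) {
      if (breath_idx > 0L) {
        gb_tv[breath_idx] <- breath_vmax - breath_v0
        tv_l <- max((breath_vmax - breath_v0) - config$V_D, 0) / 1000
        va <- (60 / breath_per) * tv_l
      }
      breath_idx <- breath_idx + 1L
      breath_t0 <- next_breath
      breath_per <- 60 / RR_eff
      breath_Ti <- config$Ti_frac * breath_per
      breath_amp <- max(A_eff * (1 + jit[min(breath_idx, max_breaths)]), 0)
      next_breath <- breath_t0 + breath_per
      breath_v0 <- V; breath_vmax <- V
      gb_t[breath_idx] <- breath_t0
      gb_amp[breath_idx] <- breath_amp
      gb_Ti[breath_idx] <- breath_Ti
      gb_per[breath_idx] <- breath_per
      gb_tv[breath_idx] <- NA_real_
    }
    if (!is.null(ventilator)) {
      # alveolar ventilation under MV from the set cycle, updated each cycle
      if (i > 1L && (t %% vent_per) < dt) {
        tv_l <- max((breath_vmax - breath_v0) - config$V_D, 0) / 1000
        va <- ventilator$rate * tv_l
        breath_v0 <- V; breath_vmax <- V
      }
    }

    pm <- p_mus_at(t)
    pm_di <- config$f_di * pm * di_scale
    pm_rc <- (1 - config$f_di) * pm
    p_drive <- p_vent_at(t) + pm_di + pm_rc + config$k_act * p_act
    Q1 <- (p_drive - V / C_rs) / config$R_aw

    # flow measurement and trigger state machine (same semantics as
    # detect_triggers on the emitted channel)
    fm <- Q1 + e_flow[i]
    flow_o[i] <- fm
    if (mode == "synchronized") {
      if (armed) {
        if (fm >= thr) {
          trig_t <- c(trig_t, t); trig_cause <- c(trig_cause, "flow-crossing")
          t_trig_active <- t; last_fire <- t; armed <- FALSE
        }
      } else if (fm < rearm_level && (t - last_fire) >= refr) {
        armed <- TRUE
      }
    } else if (mode == "independent") {
      if (sched_i <= length(sched) && t >= sched[sched_i]) {
        trig_t <- c(trig_t, sched[sched_i])
        trig_cause <- c(trig_cause, "schedule")
        t_trig_active <- t
        sched_i <- sched_i + 1L
      }
    }

    # sensor channels from start-of-step state
    p_act_eq <- config$k_act * p_act
    ppl_o[i] <- V / config$C_cw -
      (pm_di + pm_rc + (1 - config$beta_eso) * p_act_eq) + e_ppl[i]
    pab_o[i] <- config$gamma_ab * (pm_di + p_act_eq) + e_pab[i]
    ddia_o[i] <- config$k_disp * (pm_di + config$lambda_disp * p_act_eq) +
      e_ddia[i]
    pact_o[i] <- p_act + e_pact[i]

    # integrate one step: exact exponential for the regulator lag (command
    # held at its midpoint value), Heun for the compartment volume
    p_act_new <- p_act + (p_cmd_at(t + dt / 2) - p_act) * lag_fac
    pm2 <- p_mus_at(t + dt)
    p_drive2 <- p_vent_at(t + dt) +
      (config$f_di * di_scale + (1 - config$f_di)) * pm2 +
      config$k_act * p_act_new
    Q2 <- (p_drive2 - (V + 1000 * Q1 * dt) / C_rs) / config$R_aw
    V <- V + 500 * (Q1 + Q2) * dt
    p_act <- p_act_new
    if (V > breath_vmax) breath_vmax <- V

    # CO2 balance and chemoreflex drive
    paco2 <- max(paco2 + (k_gas - paco2 * va / (config$v_store * 60)) * dt,
                 1e-6)
    if (config$G_drive > 0 || config$G_rr > 0) {
      A_tgt <- config$A0 + config$G_drive * max(paco2 - config$paco2_set, 0)
      RR_tgt <- config$rr_base + config$G_rr * max(paco2 - config$paco2_set, 0)
      fac <- dt / config$tau_drive
      A_eff <- A_eff + (A_tgt - A_eff) * fac
      RR_eff <- RR_eff + (RR_tgt - RR_eff) * fac
    }
    if ((i - 1L) %% fs == 0L) {
      gas_k <- gas_k + 1L
      gas_t[gas_k] <- t
      gas_paco2[gas_k] <- paco2
    }
  }

  if (spont && breath_idx > 0L && is.na(gb_tv[breath_idx]))
    gb_tv[breath_idx] <- breath_vmax - breath_v0

  tvec <- (seq_len(n) - 1L) * dt
  rec <- waveform_record(
    t = tvec, flow = flow_o, volume = integrate_flow(flow_o, fs),
    p_pl = ppl_o, p_ab = pab_o, p_act = pact_o, d_dia = ddia_o, fs = fs,
    meta = list(scenario = scenario, seed = config$seed,
                body_mass_kg = config$body_mass, mode = mode,
                ventilated = !is.null(ventilator)))
  gas <- data.frame(t = gas_t[seq_len(gas_k)],
                    paco2 = gas_paco2[seq_len(gas_k)],
                    hco3 = config$hco3)
  gas$ph <- ph_from_gas(gas$paco2, gas$hco3)
  list(record = rec,
       triggers = data.frame(t_trigger = trig_t, cause = trig_cause,
                             armed_state_before = rep(TRUE, length(trig_t))),
       gas = gas,
       breaths_gt = data.frame(t_start = gb_t, amplitude = gb_amp,
                               Ti = gb_Ti, period = gb_per, tv_ml = gb_tv))
}
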