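#' Actuation controller configuration
#'
#' Scheduling of the PAM pressurization cycles. In `synchronized` mode a
#' trigger fires when the airway-flow signal crosses a set threshold while
#' the detector is armed; the detector then disarms and re-arms only after
#' the flow has fallen below `threshold * (1 - hysteresis)` and the
#' refractory interval has elapsed. In `independent` mode triggers fire at a
#' fixed rate regardless of the flow signal.
#'
#' @param mode `"off"`, `"independent"` or `"synchronized"`.
#' @param threshold flow threshold, l/s (in vivo titration range
#'   0.01--0.07 l/s); required > 0 in synchronized mode.
#' @param hysteresis re-arm fraction of the threshold, in `[0, 1)`
#'   (in vivo range 2--5%).
#' @param refractory minimum separation between triggers, s. Defaults to the
#'   commanded waveform cycle length: the regulator plays one full cycle per
#'   pulse.
#' @param rate actuation rate in breaths/min (independent mode).
#' @param waveform a [pressure_waveform_spec()] played per trigger.
#' @return list of class `controller_config`.
#' @export
controller_config <- function(mode = c("off", "independent", "synchronized"),
                              threshold = 0.04, hysteresis = 0.03,
                              refractory = NULL, rate = 15,
                              waveform = pressure_waveform_spec()) {
  mode <- match.arg(mode)
  if (mode == "synchronized" && (!is.finite(threshold) || threshold <= 0))
    stop("threshold must be > 0 in synchronized mode")
  if (hysteresis < 0 || hysteresis >= 1)
    stop("hysteresis must be in [0, 1)")
  if (mode == "independent" && (!is.finite(rate) || rate <= 0))
    stop("rate must be > 0 in independent mode")
  if (is.null(refractory)) refractory <- waveform_cycle_length(waveform)
  if (refractory < 0) stop("refractory must be >= 0")
  structure(list(mode = mode, threshold = threshold, hysteresis = hysteresis,
                 refractory = refractory, rate = rate, waveform = waveform),
            class = "controller_config")
}

#' Detect flow-triggered actuation events
#'
#' Causal, single-pass threshold detector with hysteresis and refractory,
#' mirroring the real-time hardware: a trigger fires at the first sample
#' where `flow >= threshold` while armed; the detector disarms on firing and
#' re-arms only once `flow < threshold * (1 - hysteresis)` AND the
#' refractory interval since the last trigger has elapsed.
#'
#' @param flow uniformly sampled flow, l/s.
#' @param fs sampling rate, Hz.
#' @param config a [controller_config()] in synchronized mode.
#' @param t0 time of the first sample, s (default 0).
#' @return data.frame of trigger events with columns `t_trigger`, `cause`
#'   (`"flow-crossing"`), `armed_state_before`.
#' @export
detect_triggers <- function(flow, fs, config, t0 = 0) {
  if (config$mode != "synchronized")
    stop("detect_triggers requires a synchronized-mode controller")
  if (length(flow) == 0L) stop("empty flow series")
  if (config$threshold <= 0) stop("threshold must be > 0")
  rearm_level <- config$threshold * (1 - config$hysteresis)
  refr_samp <- config$refractory * fs
  armed <- TRUE
  last_fire <- -Inf
  fires <- integer(0)
  for (i in seq_along(flow)) {
    if (armed) {
      if (flow[i] >= config$threshold) {
        fires <- c(fires, i)
        last_fire <- i
        armed <- FALSE
      }
    } else if (flow[i] < rearm_level && (i - last_fire) >= refr_samp) {
      armed <- TRUE
    }
  }
  data.frame(t_trigger = t0 + (fires - 1) / fs,
             cause = rep("flow-crossing", length(fires)),
             armed_state_before = rep(TRUE, length(fires)))
}

#' Fixed-rate actuation schedule
#'
#' Trigger events at `t0 + k * 60/rate` for `k = 0, 1, ...` up to
#' `duration`, independent of any flow signal (the "manual timing" mode of
#' the control box).
#'
#' @param rate actuation rate, breaths/min, > 0.
#' @param duration record duration, s.
#' @param t0 time of the first actuation, s.
#' @return data.frame of trigger events with columns `t_trigger`, `cause`
#'   (`"schedule"`), `armed_state_before`.
#' @export
independent_schedule <- function(rate, duration, t0 = 0) {
  if (rate <= 0) stop("rate must be > 0")
  if (duration < t0) stop("duration must be >= t0")
  k <- 0:floor((duration - t0) * rate / 60)
  tt <- t0 + k * 60 / rate
  tt <- tt[tt < duration | tt == t0]
  data.frame(t_trigger = tt,
             cause = rep("schedule", length(tt)),
             armed_state_before = rep(TRUE, length(tt)))
}
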