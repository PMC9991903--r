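#' @title Pneumatic artificial muscle (PAM) model
#' @name actuator
#' @description
#' The diaphragm-assist device is a pair of McKibben-type pneumatic
#' artificial muscles implanted above the diaphragm. This module models the
#' commanded pressurization waveform played per trigger pulse, the
#' electropneumatic pressure dynamics, the classic braided-actuator static
#' force law, and the lumped coupling of actuator pressure to an equivalent
#' respiratory muscle pressure used by the simulator.
NULL

# psi -> Pa conversion
PSI_TO_PA <- 6894.757

#' Commanded pressurization waveform specification
#'
#' One cycle of pressurization and depressurization played by the
#' electropneumatic regulator each time a trigger pulse arrives.
#'
#' @param peak peak commanded pressure, psi (nominal 20).
#' @param t_rise,t_hold,t_release segment durations, s, all >= 0.
#' @param shape `"trapezoid"` (linear rise, hold, linear release) or
#'   `"raised-cosine"` (smooth hump over the whole cycle).
#' @return list of class `pressure_waveform_spec`.
#' @export
pressure_waveform_spec <- function(peak = 20, t_rise = 0.3, t_hold = 0.4,
                                   t_release = 0.3,
                                   shape = c("trapezoid", "raised-cosine")) {
  shape <- match.arg(shape)
  if (peak < 0) stop("peak must be >= 0")
  if (any(c(t_rise, t_hold, t_release) < 0)) stop("durations must be >= 0")
  structure(list(peak = peak, t_rise = t_rise, t_hold = t_hold,
                 t_release = t_release, shape = shape),
            class = "pressure_waveform_spec")
}

#' Cycle length of a pressurization waveform
#' @param spec a [pressure_waveform_spec()].
#' @return total cycle duration, s.
#' @export
waveform_cycle_length <- function(spec) {
  spec$t_rise + spec$t_hold + spec$t_release
}

#' Commanded actuator pressure at a time since trigger
#'
#' Zero at t = 0 and after the cycle completes; reaches `spec$peak`;
#' continuous throughout. Vectorized over `t_since_trigger`.
#'
#' @param spec a [pressure_waveform_spec()].
#' @param t_since_trigger seconds since the trigger pulse, >= 0.
#' @return commanded pressure, psi.
#' @export
command_waveform <- function(spec, t_since_trigger) {
  if (any(t_since_trigger < 0)) stop("t_since_trigger must be >= 0")
  t <- t_since_trigger
  cyc <- waveform_cycle_length(spec)
  if (spec$shape == "raised-cosine") {
    p <- ifelse(t >= cyc | cyc == 0, 0,
                spec$peak * 0.5 * (1 - cos(2 * pi * t / cyc)))
    return(p)
  }
  p <- numeric(length(t))
  up <- t < spec$t_rise
  p[up] <- if (spec$t_rise > 0) spec$peak * t[up] / spec$t_rise else spec$peak
  hold <- t >= spec$t_rise & t < spec$t_rise + spec$t_hold
  p[hold] <- spec$peak
  rel <- t >= spec$t_rise + spec$t_hold & t < cyc
  if (spec$t_release > 0)
    p[rel] <- spec$peak * (cyc - t[rel]) / spec$t_release
  p
}

#' Braided-actuator geometry
#'
#' Idealized McKibben geometry: resting braid diameter, resting braid angle
#' (from the long axis) and resting length.
#'
#' @param D0 resting braid diameter, m.
#' @param theta0 resting braid angle, rad, in (0, pi/2).
#' @param L0 resting length, m.
#' @return list of class `actuator_geometry`.
#' @export
actuator_geometry <- function(D0, theta0, L0 = 0.15) {
  if (!(theta0 > 0 && theta0 < pi / 2)) stop("theta0 must be in (0, pi/2)")
  if (D0 <= 0 || L0 <= 0) stop("D0 and L0 must be > 0")
  structure(list(D0 = D0, theta0 = theta0, L0 = L0),
            class = "actuator_geometry")
}

#' Default calibrated PAM geometry
#'
#' Braid angle fixed at a typical 25 degrees; the resting diameter is solved
#' in closed form so that the static force law yields 40 N of contractile
#' force at 20 psi and zero contraction, matching the bench characterization
#' of the implanted actuators. The resulting diameter (~6.7 mm) is consistent
#' with the 1/4-inch braided sleeve used to build them.
#'
#' @param force_at_nominal calibration force, N (default 40).
#' @param p_nominal calibration pressure, psi (default 20).
#' @return an [actuator_geometry()].
#' @export
default_pam_geometry <- function(force_at_nominal = 40, p_nominal = 20) {
  theta0 <- 25 * pi / 180
  k <- 3 / tan(theta0)^2 - 1 / sin(theta0)^2
  D0 <- sqrt(4 * force_at_nominal / (pi * p_nominal * PSI_TO_PA * k))
  actuator_geometry(D0 = D0, theta0 = theta0, L0 = 0.15)
}

#' Static McKibben contractile force
#'
#' Idealized braid statics (Chou--Hannaford), friction and end effects
#' ignored:
#'
#'   F = (pi * D0^2 * P / 4) * (3 (1 - eps)^2 / tan^2(theta0)
#'                              - 1 / sin^2(theta0))
#'
#' with P in Pa. Force is clamped at zero past braid lock (the contraction
#' at which the braid can shorten no further).
#'
#' @param pressure actuation pressure, psi, >= 0.
#' @param eps contraction ratio (1 - L/L0), 0 <= eps < 1.
#' @param geom an [actuator_geometry()]; default the calibrated geometry.
#' @return contractile force, N (>= 0).
#' @export
mckibben_force <- function(pressure, eps, geom = default_pam_geometry()) {
  if (any(pressure < 0)) stop("pressure must be >= 0")
  if (any(eps < 0) || any(eps >= 1)) stop("eps must be in [0, 1)")
  p_pa <- pressure * PSI_TO_PA
  f <- (pi * geom$D0^2 * p_pa / 4) *
    (3 * (1 - eps)^2 / tan(geom$theta0)^2 - 1 / sin(geom$theta0)^2)
  pmax(f, 0)
}

#' Contraction ratio at braid lock
#'
#' The analytic root of the static force law: `1 - eps =
#' 1 / (sqrt(3) cos(theta0))` (equivalently, the braid angle reaching
#' 54.7 degrees). Beyond this contraction the idealized braid produces no
#' force.
#'
#' @param geom an [actuator_geometry()].
#' @return lock contraction ratio.
#' @export
braid_lock_eps <- function(geom = default_pam_geometry()) {
  1 - 1 / (sqrt(3) * cos(geom$theta0))
}

#' First-order electropneumatic pressure dynamics
#'
#' Exponential approach of the actuator pressure toward the commanded
#' pressure, standing in for the regulator and supply line. The update is
#' the exact solution over `dt` for a constant command, so a step command
#' reaches 63.2% of its amplitude after `tau` seconds regardless of the
#' integration step.
#'
#' @param p_cmd commanded pressure, psi.
#' @param p_now current actuator pressure, psi.
#' @param tau time constant, s, > 0.
#' @param dt time step, s, > 0.
#' @return updated actuator pressure, psi.
#' @export
actuator_pressure_dynamics <- function(p_cmd, p_now, tau, dt) {
  if (tau <= 0) stop("tau must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  p_now + (p_cmd - p_now) * (1 - exp(-dt / tau))
}

#' Equivalent respiratory muscle pressure of the actuator
#'
#' Lumped linear coupling of actuator pressure to the equivalent pressure
#' the assist contributes at the diaphragm, `k_act` cmH2O per psi.
#'
#' @param p_act actuator pressure, psi, >= 0.
#' @param k_act coupling gain, cmH2O per psi.
#' @return equivalent muscle pressure, cmH2O.
#' @export
assist_pressure <- function(p_act, k_act) {
  if (any(p_act < 0)) stop("p_act must be >= 0")
  if (k_act < 0) stop("k_act must be >= 0")
  k_act * p_act
}

#' Tabulate PAM static behaviour
#'
#' Force--pressure (at zero contraction) and force--contraction (at nominal
#' pressure) tables for a geometry, as printed by the `characterize-pam`
#' command-line tool.
#'
#' @param geom an [actuator_geometry()].
#' @param pressures psi grid for the force--pressure table.
#' @param n_eps number of contraction points between 0 and braid lock.
#' @param p_nominal pressure for the force--contraction table, psi.
#' @return list of two data.frames, `force_pressure` and `force_contraction`.
#' @export
characterize_pam <- function(geom = default_pam_geometry(),
                             pressures = seq(0, 25, by = 1),
                             n_eps = 26, p_nominal = 20) {
  eps_lock <- braid_lock_eps(geom)
  eps <- seq(0, eps_lock, length.out = n_eps)
  list(
    force_pressure = data.frame(
      pressure_psi = pressures,
      force_n = mckibben_force(pressures, 0, geom)),
    force_contraction = data.frame(
      eps = eps,
      force_n = mckibben_force(p_nominal, pmin(eps, 1 - 1e-9), geom))
  )
}
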