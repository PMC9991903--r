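#' Arterial CO2 / acid-base state
#'
#' Minimal arterial gas state tracked by the simulator: PaCO2, bicarbonate
#' and the pH derived from them via the Henderson--Hasselbalch relation.
#'
#' @param paco2 arterial CO2 partial pressure, mmHg.
#' @param hco3 bicarbonate, mmol/l.
#' @return list of class `gas_state` with fields `paco2`, `hco3`, `ph`.
#' @export
gas_state <- function(paco2 = 40, hco3 = 24) {
  if (!is.finite(paco2) || paco2 <= 0) stop("paco2 must be > 0")
  if (!is.finite(hco3) || hco3 <= 0) stop("hco3 must be > 0")
  st <- list(paco2 = paco2, hco3 = hco3, ph = ph_from_gas(paco2, hco3))
  class(st) <- "gas_state"
  st
}

#' Henderson--Hasselbalch pH
#'
#' `pH = 6.1 + log10(HCO3 / (0.03 * PaCO2))`. At fixed bicarbonate the pH
#' falls monotonically as PaCO2 rises (respiratory acidosis).
#'
#' @param paco2 mmHg, > 0.
#' @param hco3 mmol/l, > 0.
#' @return pH (dimensionless).
#' @export
ph_from_gas <- function(paco2, hco3) {
  if (any(!is.finite(paco2)) || any(paco2 <= 0)) stop("paco2 must be > 0")
  if (any(!is.finite(hco3)) || any(hco3 <= 0)) stop("hco3 must be > 0")
  6.1 + log10(hco3 / (0.03 * paco2))
}

#' Advance the CO2 balance by one time step
#'
#' Single-pool CO2 balance: metabolic production fills an effective storage
#' volume while alveolar ventilation clears it in proportion to PaCO2,
#'
#'   d PaCO2 / dt = (k_prod - PaCO2 * VA) / V_store   (per minute)
#'
#' with `k_prod = 0.863 * vco2` (mmHg l/min) so the steady state is the
#' classic alveolar CO2 relation `PaCO2* = 0.863 * VCO2 / VA`. With zero
#' alveolar ventilation PaCO2 rises strictly (hypercarbia under apnoea).
#' Bicarbonate is held constant (no metabolic compensation on the minutes
#' time scale simulated here).
#'
#' @param state a [gas_state()].
#' @param va alveolar ventilation, l/min, >= 0. Computed upstream as
#'   `RR * max(TV - V_D, 0) / 1000`.
#' @param dt time step, seconds, > 0.
#' @param config list with `vco2` (ml CO2/min) and `v_store` (effective CO2
#'   storage volume, l); a full [sim_config()] works.
#' @return updated `gas_state`.
#' @export
update_gas_state <- function(state, va, dt, config) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (va < 0) stop("alveolar ventilation must be >= 0")
  k_prod <- 0.863 * config$vco2
  dpaco2 <- (k_prod - state$paco2 * va) / config$v_store * (dt / 60)
  paco2 <- max(state$paco2 + dpaco2, 1e-6)
  gas_state(paco2 = paco2, hco3 = state$hco3)
}
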