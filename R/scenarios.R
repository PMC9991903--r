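#' Packaged scenarios
#'
#' Scenario configuration files (flat YAML, one per scenario) ship with the
#' package under `extdata/scenarios`. Each file freezes the mechanical and
#' chemoreflex parameters of one surrogate subject, its controller section
#' and (for the mechanical-ventilation scenario) the ventilator settings,
#' plus a seed:
#'
#' * `subject-A`: the best-responding subject; attenuated spontaneous
#'   breathing, calibrated so the simulate-and-analyze pipeline reproduces
#'   the best responder's endpoints unassisted and under synchronized
#'   assist at 20 psi.
#' * `weak-responder`: lower actuator coupling and an active CO2
#'   chemoreflex (drive amplitude and rate rise with PaCO2).
#' * `severed-phrenic`: bilateral phrenicotomy; residual ribcage effort
#'   only, used with independent actuation for timing-alignment analyses.
#' * `mech-vent`: passive subject under positive-pressure ventilation,
#'   source of the passive chest-wall compliance line.
#'
#' @param name scenario name (file stem) or a path to a scenario YAML file.
#' @param seed optional seed overriding the frozen scenario seed.
#' @return list with elements `name`, `config` (a [sim_config()]),
#'   `controller` (a [controller_config()] or NULL), `ventilator` (a
#'   [ventilator_settings()] or NULL), `duration` (suggested record length,
#'   s).
#' @export
scenario_config <- function(name, seed = NULL) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "scenarios", paste0(name, ".yaml"),
                package = "ventsim", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("unknown scenario '", name, "' (no such file or packaged scenario)")
  y <- yaml::read_yaml(path)
  sim <- y$sim
  if (!is.null(seed)) sim$seed <- seed
  config <- do.call(sim_config, sim)
  controller <- NULL
  if (!is.null(y$controller) && !identical(y$controller$mode, "off")) {
    ctl <- y$controller
    wf <- do.call(pressure_waveform_spec, ctl$waveform)
    ctl$waveform <- wf
    controller <- do.call(controller_config, ctl)
  }
  ventilator <- if (!is.null(y$ventilator))
    do.call(ventilator_settings, y$ventilator) else NULL
  list(name = y$scenario, config = config, controller = controller,
       ventilator = ventilator,
       duration = if (!is.null(y$duration)) y$duration else 90)
}

#' List the packaged scenario names
#' @return character vector of scenario names.
#' @export
list_scenarios <- function() {
  dir <- system.file("extdata", "scenarios", package = "ventsim")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Run a packaged scenario
#'
#' Convenience wrapper: loads a scenario and simulates it, optionally
#' overriding the controller (e.g. `controller = NULL` to run the
#' `subject-A` scenario unassisted, or an independent-mode controller for
#' asynchrony experiments).
#'
#' @param name scenario name or path, see [scenario_config()].
#' @param duration record length, s; scenario default if NULL.
#' @param controller override for the scenario's controller section; the
#'   scenario's own controller if missing.
#' @param seed optional seed override.
#' @return as [simulate_subject()].
#' @export
run_scenario <- function(name, duration = NULL, controller, seed = NULL) {
  sc <- scenario_config(name, seed = seed)
  if (!missing(controller)) sc$controller <- controller
  if (is.null(duration)) duration <- sc$duration
  simulate_subject(sc$config, controller = sc$controller,
                   ventilator = sc$ventilator, duration = duration,
                   scenario = sc$name)
}
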