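#' Analyze a waveform record
#'
#' The full waveform-analysis pass: breath segmentation from the volume
#' channel, per-breath ventilation features, actuation-onset detection and
#' breath--actuation alignment, pressure normalization to the breath-bound
#' baseline, per-breath pressure deltas, minute ventilation, and the
#' timing--outcome regressions (when enough matched breaths exist).
#'
#' @param rec a [waveform_record()].
#' @param window analysis window `c(t0, t1)` in s; whole record if NULL.
#' @param min_separation,min_prominence segmentation parameters, see
#'   [segment_breaths()].
#' @param onset_threshold actuation-onset threshold, psi.
#' @return list of class `breath_analysis`:
#'   `breaths` -- one row per breath (landmarks, TV, PIF, timing metrics,
#'   pressure deltas, `in_window`);
#'   `summary` -- list with `n_breaths`, `mv_l_min`, `mv_ml_min_kg`,
#'   `mean_tv_ml`, `mean_pif_lps`, `mean_rr`, `mean_d_dia_cm` (per-breath
#'   peak displacement, if the channel exists), mean pressure deltas, and
#'   regressions `tv_on_dt_vpk_p0`, `tv_on_dt_p0_v0`, `pif_on_dt_vpk_p0`
#'   (NULL when < 3 matched breaths);
#'   `segments` -- the raw segmentation table.
#' @export
analyze_record <- function(rec, window = NULL, min_separation = 0.5,
                           min_prominence = 5, onset_threshold = 1) {
  if (is.null(window)) window <- c(rec$t[1], rec$t[length(rec$t)])
  segs <- segment_breaths(rec$volume, rec$fs, min_separation, min_prominence,
                          flow = rec$flow, t0 = rec$t[1])
  feats <- breath_features(segs, rec$flow, rec$volume, rec$fs)
  events <- detect_actuation_onsets(rec$p_act, rec$fs, onset_threshold,
                                    t0 = rec$t[1])
  feats <- align_actuations(feats, events)
  ppl_n <- normalize_pressure(rec$p_pl, segs)
  pab_n <- normalize_pressure(rec$p_ab, segs)
  deltas <- pressure_deltas(segs, ppl_n, pab_n)
  breaths <- cbind(feats, deltas)
  breaths$d_dia_peak <- if (!is.null(rec$d_dia) && nrow(segs))
    mapply(function(a, b) max(rec$d_dia[a:(b - 1L)]) - rec$d_dia[a],
           segs$i_start, segs$i_end)
  else rep(NA_real_, nrow(breaths))
  breaths$in_window <- breaths$t_V0 >= window[1] & breaths$t_V0 < window[2]

  inw <- breaths[breaths$in_window, , drop = FALSE]
  mv <- if (nrow(inw)) minute_ventilation(inw, window, rec$meta$body_mass_kg)
        else list(mv_l_min = 0, mv_ml_min_kg = NA_real_, n_breaths = 0L)
  reg <- function(x, y) {
    ok <- sum(is.finite(x) & is.finite(y)) >= 3 &&
      stats::var(x[is.finite(x)]) > 0
    if (ok) fit_timing_regression(x, y) else NULL
  }
  summary <- list(
    n_breaths = nrow(inw),
    mv_l_min = mv$mv_l_min,
    mv_ml_min_kg = mv$mv_ml_min_kg,
    mean_tv_ml = if (nrow(inw)) mean(inw$TV) else NA_real_,
    mean_pif_lps = if (nrow(inw)) mean(inw$PIF) else NA_real_,
    mean_rr = if (nrow(inw)) mean(inw$rr_inst) else NA_real_,
    mean_d_dia_cm = if (nrow(inw)) mean(inw$d_dia_peak) else NA_real_,
    mean_dppl = if (nrow(inw)) mean(inw$dPpl) else NA_real_,
    mean_dpab = if (nrow(inw)) mean(inw$dPab) else NA_real_,
    mean_dpdi = if (nrow(inw)) mean(inw$dPdi) else NA_real_,
    n_matched = sum(inw$matched),
    tv_on_dt_vpk_p0 = reg(inw$dt_Vpk_P0, inw$TV),
    tv_on_dt_p0_v0 = reg(inw$dt_P0_V0, inw$TV),
    pif_on_dt_vpk_p0 = reg(inw$dt_Vpk_P0, inw$PIF),
    window = window)
  structure(list(breaths = breaths, summary = summary, segments = segs),
            class = "breath_analysis")
}

#' Campbell-diagram work of breathing for a record
#'
#' Segments the target record, normalizes its pleural pressure, builds the
#' PV loops and computes per-breath WOB against a chest-wall compliance line
#' fitted from a mechanical-ventilation record.
#'
#' @param rec target [waveform_record()] (spontaneous or assisted breathing).
#' @param mv_rec mechanical-ventilation [waveform_record()] for the
#'   compliance fit (or a ready `compliance_fit` object).
#' @param window,mv_window analysis windows `c(t0, t1)`, s; full records if
#'   NULL.
#' @param min_separation,min_prominence segmentation parameters.
#' @return list: `fit` (the `compliance_fit`), `wob` (see [wob_summary()]).
#' @export
wob_analysis <- function(rec, mv_rec, window = NULL, mv_window = NULL,
                         min_separation = 0.5, min_prominence = 5) {
  crop <- function(r, w) {
    if (is.null(w)) return(r)
    keep <- r$t >= w[1] & r$t < w[2]
    waveform_record(t = r$t[keep] - r$t[keep][1], flow = r$flow[keep],
                    volume = r$volume[keep], p_pl = r$p_pl[keep],
                    p_ab = r$p_ab[keep], p_act = r$p_act[keep],
                    d_dia = r$d_dia[keep], fs = r$fs, meta = r$meta)
  }
  fit <- if (inherits(mv_rec, "compliance_fit")) mv_rec else {
    mvr <- crop(mv_rec, mv_window)
    mseg <- segment_breaths(mvr$volume, mvr$fs, min_separation,
                            min_prominence)
    mppl <- normalize_pressure(mvr$p_pl, mseg)
    fit_chest_wall_compliance(pv_loops(mseg, mppl, mvr$volume))
  }
  tr <- crop(rec, window)
  segs <- segment_breaths(tr$volume, tr$fs, min_separation, min_prominence)
  ppl <- normalize_pressure(tr$p_pl, segs)
  list(fit = fit, wob = wob_summary(pv_loops(segs, ppl, tr$volume), fit))
}

#' Run the full simulate-and-analyze pipeline
#'
#' Simulates a packaged (or file-based) scenario, analyzes the record, and
#' optionally writes the artefact bundle: waveform CSV (+ JSON sidecar),
#' per-breath table CSV, and a summary JSON embedding the scenario name,
#' seed and package version. Deterministic given the seed.
#'
#' @param scenario scenario name or YAML path, see [scenario_config()].
#' @param duration record length, s (scenario default if NULL).
#' @param out_dir output directory; no files are written when NULL.
#' @param controller optional controller override (e.g. NULL for assist-off).
#' @param seed optional seed override.
#' @param window analysis window, see [analyze_record()].
#' @return list: `sim` (see [simulate_subject()]), `analysis` (see
#'   [analyze_record()]), `summary` (the summary list, plus provenance and
#'   an `apnoea_alert` flag when minute ventilation falls below 0.5 l/min),
#'   `paths` (written files, if any).
#' @export
run_pipeline <- function(scenario, duration = NULL, out_dir = NULL,
                         controller, seed = NULL, window = NULL) {
  sc <- scenario_config(scenario, seed = seed)
  if (!missing(controller)) sc$controller <- controller
  if (is.null(duration)) duration <- sc$duration
  sim <- simulate_subject(sc$config, controller = sc$controller,
                          ventilator = sc$ventilator, duration = duration,
                          scenario = sc$name)
  analysis <- analyze_record(sim$record, window = window)
  summary <- analysis$summary
  summary$scenario <- sc$name
  summary$seed <- sc$config$seed
  summary$package_version <- as.character(utils::packageVersion("ventsim"))
  summary$apnoea_alert <- summary$mv_l_min < 0.5
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      waveform = file.path(out_dir, paste0(sc$name, "-waveform.csv")),
      breaths = file.path(out_dir, paste0(sc$name, "-breaths.csv")),
      summary = file.path(out_dir, paste0(sc$name, "-summary.json")))
    write_waveform(sim$record, paths$waveform)
    utils::write.csv(analysis$breaths, paths$breaths, row.names = FALSE)
    drop <- vapply(summary, is.list, logical(1))
    jsonlite::write_json(c(summary[!drop],
                           lapply(summary[drop], unclass)),
                         paths$summary, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  list(sim = sim, analysis = analysis, summary = summary, paths = paths)
}
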