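#' Multichannel respiratory waveform record
#'
#' The universal currency of the package: a uniformly sampled multichannel
#' recording of airway flow, integrated volume, pleural- and abdominal-
#' surrogate pressures, actuator pressure and (optionally) caudal diaphragm
#' displacement, as acquired in the instrumented animal at 1000 Hz.
#'
#' @param t numeric vector, seconds from record start (uniform, starting at 0).
#' @param flow airway flow in l/s, inspiratory positive.
#' @param volume lung volume above the record-start reference, ml.
#' @param p_pl pleural-surrogate (oesophageal balloon) pressure, cmH2O.
#' @param p_ab abdominal-surrogate (gastric balloon) pressure, cmH2O.
#' @param p_act actuator pressure, psi.
#' @param d_dia optional caudal diaphragm displacement, cm.
#' @param fs sampling rate in Hz.
#' @param meta free-form provenance list (scenario name, seed, body mass kg).
#'
#' @return An object of class `waveform_record`: a list with the channel
#'   vectors, `fs` and `meta`.
#' @export
waveform_record <- function(t, flow, volume, p_pl, p_ab, p_act,
                            d_dia = NULL, fs = 1000, meta = list()) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  n <- length(t)
  chans <- list(flow = flow, volume = volume, p_pl = p_pl,
                p_ab = p_ab, p_act = p_act)
  if (!is.null(d_dia)) chans$d_dia <- d_dia
  for (nm in names(chans)) {
    if (length(chans[[nm]]) != n)
      stop("channel '", nm, "' has length ", length(chans[[nm]]),
           " but t has length ", n)
    if (anyNA(chans[[nm]]) && nm != "d_dia")
      stop("NaN/NA in required channel '", nm, "'")
  }
  if (n >= 2) {
    dt <- diff(t)
    if (any(abs(dt - 1 / fs) > 1e-6 / fs))
      stop("time vector is not uniform at fs = ", fs, " Hz")
  }
  rec <- c(list(fs = fs, t = t), chans, list(meta = meta))
  class(rec) <- "waveform_record"
  rec
}

#' @export
print.waveform_record <- function(x, ...) {
  cat("<waveform_record> ", length(x$t), " samples @ ", x$fs, " Hz (",
      sprintf("%.1f", length(x$t) / x$fs), " s)\n", sep = "")
  cat("  channels:", paste(setdiff(names(x), c("fs", "t", "meta")),
                           collapse = ", "), "\n")
  if (!is.null(x$meta$scenario))
    cat("  scenario:", x$meta$scenario, "\n")
  invisible(x)
}

#' Cumulative trapezoidal integral of flow, in ml
#'
#' Integrates an airway-flow channel (l/s) over a uniform time base into a
#' volume channel (ml) above the record-start reference. This is the same
#' quadrature the simulator uses to emit its volume channel, so simulator
#' output satisfies the flow--volume conservation invariant exactly.
#'
#' @param flow flow samples, l/s.
#' @param fs sampling rate, Hz.
#' @return numeric vector of volumes, ml; first element 0.
#' @export
integrate_flow <- function(flow, fs) {
  n <- length(flow)
  if (n == 0L) return(numeric(0))
  dt <- 1 / fs
  c(0, cumsum((flow[-n] + flow[-1]) / 2 * dt)) * 1000
}

#' Validate the flow--volume conservation invariant of a record
#'
#' @param rec a `waveform_record`.
#' @param tol maximum absolute deviation per sample, ml.
#' @return TRUE invisibly; error if the invariant fails.
#' @export
check_flow_volume <- function(rec, tol = 0.1) {
  v <- integrate_flow(rec$flow, rec$fs)
  dev <- max(abs(v - (rec$volume - rec$volume[1])))
  if (dev > tol)
    stop(sprintf("volume deviates from integrated flow by %.3g ml", dev))
  invisible(TRUE)
}
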