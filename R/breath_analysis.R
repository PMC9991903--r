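#' Segment breaths from a volume waveform
#'
#' Breath bounds are the interior local minima of the volume channel (the
#' locations of V0), filtered by a topographic prominence criterion and a
#' minimum separation. Within each breath the start of expiration (Vpk) is
#' the argmax of volume and Fpk the argmax of flow over the inspiratory
#' window.
#'
#' The rule, applied verbatim: a candidate bound is a sample strictly below
#' both neighbours; its prominence is `min(maxL, maxR) - v[i]` where `maxL`
#' (`maxR`) is the running maximum walking left (right) until a sample below
#' `v[i]` or the series end is reached, capped at `min_prominence` (only the
#' threshold comparison matters). Candidates with prominence below
#' `min_prominence` are dropped; remaining candidates are accepted in order
#' of increasing volume, skipping any within `min_separation` of an accepted
#' bound. Consecutive accepted bounds delimit breaths (half-open index
#' ranges), which tile the analysis window without overlap.
#'
#' @param volume volume samples, ml.
#' @param fs sampling rate, Hz.
#' @param min_separation minimum time between bounds, s.
#' @param min_prominence minimum prominence of a bound, ml.
#' @param flow optional flow channel (l/s) used to locate Fpk.
#' @param t0 time of the first sample, s.
#' @return data.frame of breath segments: `i_start`, `i_end` (1-based,
#'   half-open `[i_start, i_end)`), `t_V0`, `t_Vpk`, `t_Fpk` (NA without a
#'   flow channel). Zero rows if fewer than two bounds are found.
#' @export
segment_breaths <- function(volume, fs, min_separation = 0.5,
                            min_prominence = 5, flow = NULL, t0 = 0) {
  n <- length(volume)
  if (n <= 2 * min_separation * fs)
    stop("series shorter than twice min_separation")
  bounds <- find_volume_minima(volume, fs, min_separation, min_prominence)
  if (length(bounds) < 2L)
    return(data.frame(i_start = integer(0), i_end = integer(0),
                      i_Vpk = integer(0), i_Fpk = integer(0),
                      t_V0 = numeric(0), t_Vpk = numeric(0),
                      t_Fpk = numeric(0)))
  i_start <- bounds[-length(bounds)]
  i_end <- bounds[-1]
  i_vpk <- as.integer(mapply(
    function(a, b) a + which.max(volume[a:(b - 1L)]) - 1L, i_start, i_end))
  i_fpk <- if (is.null(flow)) rep(NA_integer_, length(i_start)) else
    as.integer(mapply(function(a, p) a + which.max(flow[a:p]) - 1L,
                      i_start, i_vpk))
  data.frame(i_start = i_start, i_end = i_end,
             i_Vpk = i_vpk, i_Fpk = i_fpk,
             t_V0 = t0 + (i_start - 1L) / fs,
             t_Vpk = t0 + (i_vpk - 1L) / fs,
             t_Fpk = t0 + (i_fpk - 1L) / fs)
}

#' Locate prominent local minima of a volume series
#'
#' The bound-detection core of [segment_breaths()]; exposed for testing
#' against an exhaustive oracle.
#'
#' @inheritParams segment_breaths
#' @return sorted integer vector of bound indices (1-based).
#' @export
find_volume_minima <- function(volume, fs, min_separation = 0.5,
                               min_prominence = 5) {
  n <- length(volume)
  if (n < 3L) return(integer(0))
  v <- volume
  cand <- which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] < v[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom_ok <- function(i) {
    vi <- v[i]
    need <- vi + min_prominence
    mx <- -Inf
    j <- i - 1L
    while (j >= 1L) {
      if (v[j] < vi) break
      if (v[j] > mx) {
        mx <- v[j]
        if (mx >= need) break
      }
      j <- j - 1L
    }
    if (mx < need) return(FALSE)
    mx <- -Inf
    j <- i + 1L
    while (j <= n) {
      if (v[j] < vi) break
      if (v[j] > mx) {
        mx <- v[j]
        if (mx >= need) break
      }
      j <- j + 1L
    }
    mx >= need
  }
  cand <- cand[vapply(cand, prom_ok, logical(1))]
  if (!length(cand)) return(integer(0))
  sep <- min_separation * fs
  kept <- integer(0)
  for (i in cand[order(v[cand], cand)]) {
    if (!length(kept) || all(abs(kept - i) >= sep)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Per-breath ventilation features
#'
#' Tidal volume `TV = V(t_Vpk) - V(t_V0)`, peak inspiratory flow over the
#' inspiratory window `[t_V0, t_Vpk]`, inspiratory time, total breath time
#' and instantaneous respiratory rate `60 / Ttot`.
#'
#' @param segments data.frame from [segment_breaths()].
#' @param flow flow channel, l/s.
#' @param volume volume channel, ml.
#' @param fs sampling rate, Hz.
#' @return data.frame: one row per breath with `t_V0`, `t_Vpk`, `t_Fpk`,
#'   `TV` (ml), `PIF` (l/s), `Ti`, `Ttot` (s), `rr_inst` (breaths/min).
#' @export
breath_features <- function(segments, flow, volume, fs) {
  n <- length(volume)
  if (nrow(segments) &&
      (max(segments$i_end) - 1L > n || min(segments$i_start) < 1L))
    stop("segment indices out of range")
  if (!nrow(segments))
    return(data.frame(t_V0 = numeric(0), t_Vpk = numeric(0),
                      t_Fpk = numeric(0), TV = numeric(0), PIF = numeric(0),
                      Ti = numeric(0), Ttot = numeric(0),
                      rr_inst = numeric(0)))
  i_vpk <- segments$i_Vpk
  tv <- volume[i_vpk] - volume[segments$i_start]
  pif <- mapply(function(a, p) max(flow[a:p]), segments$i_start, i_vpk)
  ttot <- (segments$i_end - segments$i_start) / fs
  data.frame(t_V0 = segments$t_V0, t_Vpk = segments$t_Vpk,
             t_Fpk = segments$t_Fpk,
             TV = pmax(tv, 0), PIF = pmax(pif, 0),
             Ti = segments$t_Vpk - segments$t_V0, Ttot = ttot,
             rr_inst = 60 / ttot)
}

#' Minute ventilation over a time window
#'
#' Sum of the tidal volumes of breaths whose start of inspiration falls
#' inside the window, scaled to one minute, plus the body-weight-normalized
#' value.
#'
#' @param features data.frame from [breath_features()].
#' @param window numeric length-2: window start and end, s.
#' @param body_mass kg; NA normalized value if omitted.
#' @return list: `mv_l_min` (l/min), `mv_ml_min_kg` (ml/min/kg), `n_breaths`.
#'   An empty window yields zero with a warning.
#' @export
minute_ventilation <- function(features, window, body_mass = NULL) {
  stopifnot(length(window) == 2L, diff(window) > 0)
  sel <- features$t_V0 >= window[1] & features$t_V0 < window[2]
  if (!any(sel)) {
    warning("no breaths start inside the window; minute ventilation 0")
    return(list(mv_l_min = 0,
                mv_ml_min_kg = if (is.null(body_mass)) NA_real_ else 0,
                n_breaths = 0L))
  }
  mv <- sum(features$TV[sel]) / 1000 * 60 / diff(window)
  list(mv_l_min = mv,
       mv_ml_min_kg = if (is.null(body_mass)) NA_real_ else
         mv * 1000 / body_mass,
       n_breaths = sum(sel))
}

#' Detect actuation onsets from the actuator-pressure channel
#'
#' P0 is the first sample of each rising excursion above `onset_threshold`
#' after the channel has returned below it; `p_peak` is the maximum within
#' the excursion. The detector debounces with a release level a fraction
#' `hysteresis` below the onset threshold, so sensor noise while the slow
#' pressure signal sits near the threshold cannot split one pressurization
#' cycle into several events.
#'
#' @param p_act actuator pressure channel, psi.
#' @param fs sampling rate, Hz.
#' @param onset_threshold psi, above the sensor noise floor (default 1).
#' @param hysteresis release fraction: an excursion ends once the channel
#'   falls below `onset_threshold * (1 - hysteresis)`.
#' @param t0 time of the first sample, s.
#' @return data.frame of events: `t_P0` (s), `p_peak` (psi). May be empty.
#' @export
detect_actuation_onsets <- function(p_act, fs, onset_threshold = 1,
                                    hysteresis = 0.5, t0 = 0) {
  release <- onset_threshold * (1 - hysteresis)
  onsets <- integer(0)
  peaks <- numeric(0)
  in_exc <- FALSE
  pk <- -Inf
  for (i in seq_along(p_act)) {
    if (!in_exc) {
      if (p_act[i] >= onset_threshold) {
        in_exc <- TRUE
        onsets <- c(onsets, i)
        pk <- p_act[i]
      }
    } else if (p_act[i] < release) {
      in_exc <- FALSE
      peaks <- c(peaks, pk)
    } else if (p_act[i] > pk) {
      pk <- p_act[i]
    }
  }
  if (in_exc) peaks <- c(peaks, pk)
  data.frame(t_P0 = t0 + (onsets - 1L) / fs, p_peak = peaks)
}

#' Match breaths to actuation events and compute timing metrics
#'
#' Each breath is matched to the unique actuation whose onset P0 falls in
#' `[t_V0 - Ttot/2, t_Vpk + Ttot/2)`; breaths with zero or multiple
#' candidate actuations are flagged unmatched and carry NA metrics (they are
#' excluded from the timing regressions).
#'
#' @param features data.frame from [breath_features()] (time-ordered).
#' @param events data.frame from [detect_actuation_onsets()] (time-ordered).
#' @return `features` with appended columns `matched`, `t_P0`, `p_peak`,
#'   `dt_Vpk_P0` (`t_Vpk - t_P0`, s) and `dt_P0_V0` (`t_P0 - t_V0`, s).
#' @export
align_actuations <- function(features, events) {
  nb <- nrow(features)
  out <- features
  out$matched <- rep(FALSE, nb)
  out$t_P0 <- out$p_peak <- out$dt_Vpk_P0 <- out$dt_P0_V0 <- rep(NA_real_, nb)
  if (!nb || !nrow(events)) return(out)
  for (b in seq_len(nb)) {
    lo <- features$t_V0[b] - features$Ttot[b] / 2
    hi <- features$t_Vpk[b] + features$Ttot[b] / 2
    hit <- which(events$t_P0 >= lo & events$t_P0 < hi)
    if (length(hit) == 1L) {
      out$matched[b] <- TRUE
      out$t_P0[b] <- events$t_P0[hit]
      out$p_peak[b] <- events$p_peak[hit]
      out$dt_Vpk_P0[b] <- features$t_Vpk[b] - events$t_P0[hit]
      out$dt_P0_V0[b] <- events$t_P0[hit] - features$t_V0[b]
    }
  }
  out
}

#' Normalize a pressure channel to its breath-bound baseline
#'
#' Subtracts the mean of the samples at the breath-bound instants (the
#' segment boundaries), so the pressure reading at the bounds averages to
#' zero over the analysis window and per-breath changes are read relative to
#' a common baseline.
#'
#' @param series pressure samples.
#' @param segments data.frame from [segment_breaths()]; with zero rows the
#'   series is returned unchanged with a warning.
#' @return normalized series.
#' @export
normalize_pressure <- function(series, segments) {
  if (!nrow(segments)) {
    warning("no segments; returning series unchanged")
    return(series)
  }
  idx <- unique(c(segments$i_start, segments$i_end[nrow(segments)]))
  idx <- idx[idx >= 1 & idx <= length(series)]
  series - mean(series[idx])
}

#' Per-breath pressure deltas
#'
#' The maximum change in pressure per breath, relative to the per-breath
#' baseline (mean of the channel at the breath's two bounds): for pleural
#' pressure the signed largest-magnitude excursion (negative for
#' spontaneous/assisted breaths, positive under mechanical ventilation); for
#' abdominal pressure the peak rise; for transdiaphragmatic pressure the
#' peak rise of the sample-wise difference channel `Pdi = Pab - Ppl`.
#'
#' @param segments data.frame from [segment_breaths()].
#' @param p_pl,p_ab normalized pressure channels, cmH2O.
#' @return data.frame: `dPpl`, `dPab`, `dPdi` (cmH2O), one row per breath.
#' @export
pressure_deltas <- function(segments, p_pl, p_ab) {
  n <- length(p_pl)
  if (nrow(segments) &&
      (max(segments$i_end) - 1L > n || min(segments$i_start) < 1L))
    stop("segment outside series")
  if (!nrow(segments))
    return(data.frame(dPpl = numeric(0), dPab = numeric(0),
                      dPdi = numeric(0)))
  p_di <- p_ab - p_pl
  one <- function(a, b) {
    ii <- a:(b - 1L)
    bidx <- c(a, min(b, n))
    base_pl <- mean(p_pl[bidx]); base_ab <- mean(p_ab[bidx])
    base_di <- mean(p_di[bidx])
    exc <- p_pl[ii] - base_pl
    c(dPpl = exc[which.max(abs(exc))],
      dPab = max(p_ab[ii] - base_ab),
      dPdi = max(p_di[ii] - base_di))
  }
  res <- t(mapply(one, segments$i_start, segments$i_end))
  out <- as.data.frame(res)
  names(out) <- c("dPpl", "dPab", "dPdi")
  out
}

#' Ordinary least-squares timing regression
#'
#' Regression of a per-breath outcome (tidal volume or peak inspiratory
#' flow) on a timing-alignment metric, as used to relate actuation timing to
#' breath outcomes. Stock OLS via [stats::lm()].
#'
#' @param x predictor (e.g. `dt_Vpk_P0`), NA pairs dropped.
#' @param y outcome (e.g. `TV`).
#' @return list of class `regression_result`: `slope`, `intercept`, `r2`,
#'   `p_value` (two-sided slope test), `n`.
#' @export
fit_timing_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 matched breaths")
  if (stats::var(x) == 0) stop("degenerate predictor: zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, intercept %.4g, r2 %.3f, p %.3g, n %d\n",
              x$slope, x$intercept, x$r2, x$p_value, x$n))
  invisible(x)
}
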