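#' Pleural pressure--volume loops for a Campbell diagram
#'
#' Builds one PV loop per breath from the (normalized) pleural pressure and
#' volume channels, split into an inspiratory limb (`i_start` to the volume
#' peak) and an expiratory limb (volume peak to `i_end`).
#'
#' @param segments data.frame from [segment_breaths()].
#' @param p_pl normalized pleural pressure channel, cmH2O.
#' @param volume volume channel, ml.
#' @return list of `pv_loop` objects: each a list with data.frames
#'   `inspiratory` and `expiratory` (columns `p_pl`, `volume`) and `tv_ml`.
#' @export
pv_loops <- function(segments, p_pl, volume) {
  stopifnot(length(p_pl) == length(volume))
  lapply(seq_len(nrow(segments)), function(b) {
    a <- segments$i_start[b]; pk <- segments$i_Vpk[b]
    e <- min(segments$i_end[b], length(volume))
    loop <- list(
      inspiratory = data.frame(p_pl = p_pl[a:pk], volume = volume[a:pk]),
      expiratory = data.frame(p_pl = p_pl[pk:e], volume = volume[pk:e]),
      tv_ml = volume[pk] - volume[a])
    class(loop) <- "pv_loop"
    loop
  })
}

#' Fit the passive chest-wall compliance line
#'
#' Least-squares line of volume on pleural pressure pooled over the
#' inspiratory limbs of mechanical-ventilation PV loops (passive inflation;
#' expiratory limbs are excluded to avoid hysteresis bias). Under passive
#' positive-pressure inflation the pleural pressure tracks the chest-wall
#' elastic recoil, so the fitted slope estimates chest-wall compliance.
#'
#' @param mv_loops list of `pv_loop` from a mechanical-ventilation record.
#' @return list of class `compliance_fit`: `C_cw_fit` (ml/cmH2O),
#'   `intercept` (ml), `r2`, `n_breaths`.
#' @export
fit_chest_wall_compliance <- function(mv_loops) {
  if (!length(mv_loops)) stop("need at least one MV breath")
  p <- unlist(lapply(mv_loops, function(l) l$inspiratory$p_pl))
  v <- unlist(lapply(mv_loops, function(l) l$inspiratory$volume))
  if (stats::var(p) == 0) stop("zero pressure variance in MV limbs")
  fit <- stats::lm(v ~ p)
  structure(list(C_cw_fit = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = summary(fit)$r.squared,
                 n_breaths = length(mv_loops)),
            class = "compliance_fit")
}

#' Campbell-diagram work of breathing for one loop
#'
#' The work of one breath is the area between the inspiratory limb of the
#' pleural PV loop and the passive chest-wall compliance line spanning the
#' same volume range. The line is evaluated at the limb's volume samples;
#' the enclosed region is integrated in volume, splitting at crossings of
#' the limb and the line and summing the absolute areas of the sub-regions.
#' Converted at 1 cmH2O l = 0.0980665 J.
#'
#' @param loop a `pv_loop`.
#' @param fit a `compliance_fit`.
#' @return list of class `wob_result`: `work` (J), `work_per_litre` (J/l),
#'   `tv_ml`.
#' @export
campbell_wob <- function(loop, fit) {
  limb <- loop$inspiratory
  if (loop$tv_ml <= 0) stop("loop has zero tidal volume")
  # pressure distance between the compliance line and the limb at each
  # sampled volume: p_line(v) = (v - intercept) / C_cw_fit
  d <- (limb$volume - fit$intercept) / fit$C_cw_fit - limb$p_pl
  v <- limb$volume
  nn <- length(v)
  area <- 0  # cmH2O * ml, absolute by sub-region
  seg_area <- 0
  for (i in seq_len(nn - 1L)) {
    dv <- v[i + 1L] - v[i]
    d1 <- d[i]; d2 <- d[i + 1L]
    if (d1 == 0 && d2 == 0) next
    if (d1 * d2 < 0) {
      # limb crosses the line inside the interval: split at the root
      f <- d1 / (d1 - d2)
      seg_area <- seg_area + d1 * f * dv / 2
      area <- area + abs(seg_area)
      seg_area <- d2 * (1 - f) * dv / 2
    } else {
      seg_area <- seg_area + (d1 + d2) / 2 * dv
    }
  }
  area <- area + abs(seg_area)
  work <- area / 1000 * 0.0980665  # cmH2O*ml -> cmH2O*l -> J
  structure(list(work = work,
                 work_per_litre = work / (loop$tv_ml / 1000),
                 tv_ml = loop$tv_ml),
            class = "wob_result")
}

#' Work of breathing for a set of breaths
#'
#' Applies [campbell_wob()] per breath and summarizes. The headline figure
#' is the per-breath mean of work per litre; the pooled alternative (total
#' work over total volume) is reported alongside.
#'
#' @param loops list of `pv_loop`.
#' @param fit a `compliance_fit`.
#' @param min_tv_ml breaths below this tidal volume are skipped (degenerate
#'   loops), default 1 ml.
#' @return list: `wob_per_breath` (data.frame `work_j`, `work_per_litre`,
#'   `tv_ml`), `mean_work_per_litre` (J/l), `pooled_work_per_litre` (J/l),
#'   `n_breaths`.
#' @export
wob_summary <- function(loops, fit, min_tv_ml = 1) {
  loops <- Filter(function(l) l$tv_ml >= min_tv_ml, loops)
  if (!length(loops)) stop("no loops with usable tidal volume")
  per <- lapply(loops, campbell_wob, fit = fit)
  df <- data.frame(work_j = vapply(per, `[[`, numeric(1), "work"),
                   work_per_litre = vapply(per, `[[`, numeric(1),
                                           "work_per_litre"),
                   tv_ml = vapply(per, `[[`, numeric(1), "tv_ml"))
  list(wob_per_breath = df,
       mean_work_per_litre = mean(df$work_per_litre),
       pooled_work_per_litre = sum(df$work_j) / (sum(df$tv_ml) / 1000),
       n_breaths = nrow(df))
}
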