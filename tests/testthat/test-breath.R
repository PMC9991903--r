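test_that("sinusoidal volume segments at the analytic minima", {
  fs <- 1000
  tt <- seq(0, 20, by = 1 / fs)
  vol <- 100 * (1 - cos(2 * pi * 0.25 * tt))  # minima at 0, 4, 8, 12, 16, 20
  segs <- segment_breaths(vol, fs)
  # interior minima at 4, 8, 12, 16 s tile three complete breaths
  expect_equal(nrow(segs), 3)
  expect_equal(segs$t_V0, c(4, 8, 12), tolerance = 2 / fs)
  expect_equal(segs$t_Vpk - segs$t_V0, rep(2, 3), tolerance = 2 / fs)
})

test_that("constant volume yields no breaths; short series rejected", {
  expect_equal(nrow(segment_breaths(rep(5, 4000), 1000)), 0)
  expect_error(segment_breaths(rep(5, 100), 1000))
})

test_that("bound detection equals the exhaustive scan oracle", {
  set.seed(31)
  fs <- 100
  tt <- seq(0, 40, by = 1 / fs)
  for (k in 1:5) {
    f1 <- runif(1, 0.2, 0.35); f2 <- runif(1, 0.05, 0.12)
    vol <- 80 * (1 - cos(2 * pi * f1 * tt)) +
      30 * sin(2 * pi * f2 * tt) + rnorm(length(tt), 0, 2)
    for (prom in c(5, 25)) {
      got <- find_volume_minima(vol, fs, 0.5, prom)
      expect_identical(got, oracle_volume_minima(vol, fs, 0.5, prom))
    }
  }
})

test_that("breath features recover constructed fixture arithmetic", {
  fs <- 100
  # asymmetric triangular breaths: rise 150 ml over 1 s, fall over 3 s
  tt <- seq(0, 20, by = 1 / fs)
  ph <- tt %% 4
  vol <- ifelse(ph < 1, 150 * ph, 150 * (4 - ph) / 3)
  flow <- c(0, diff(vol)) * fs / 1000
  segs <- segment_breaths(vol, fs, flow = flow)
  feats <- breath_features(segs, flow, vol, fs)
  expect_equal(nrow(feats), 3)
  expect_equal(feats$TV, rep(150, 3), tolerance = 0.5)
  expect_equal(feats$rr_inst, rep(15, 3), tolerance = 0.1)
  expect_equal(feats$Ttot, rep(4, 3), tolerance = 0.05)
  expect_equal(feats$Ti, rep(1, 3), tolerance = 0.05)
  # zero flow inside a segment gives TV = 0, PIF = 0
  z <- breath_features(data.frame(i_start = 1L, i_end = 200L, i_Vpk = 100L,
                                  i_Fpk = 1L, t_V0 = 0, t_Vpk = 1, t_Fpk = 0),
                       flow = rep(0, 300), volume = rep(10, 300), fs = fs)
  expect_equal(z$TV, 0)
  expect_equal(z$PIF, 0)
  # linearity: scaling volume doubles TV, leaves timing unchanged
  f2 <- breath_features(segs, flow, 2 * vol, fs)
  expect_equal(f2$TV, 2 * feats$TV)
  expect_equal(f2$Ti, feats$Ti)
  expect_error(breath_features(data.frame(i_start = 1L, i_end = 9999L,
                                          i_Vpk = 5L, i_Fpk = 1L, t_V0 = 0,
                                          t_Vpk = 1, t_Fpk = 0),
                               flow, vol, fs))
})

test_that("minute ventilation arithmetic and normalization", {
  feats <- data.frame(t_V0 = seq(1, 29, length.out = 8), TV = rep(100, 8))
  mv <- minute_ventilation(feats, c(0, 30))
  expect_equal(mv$mv_l_min, 1.6)
  mv2 <- minute_ventilation(feats, c(0, 30), body_mass = 40)
  expect_equal(mv2$mv_ml_min_kg, 40)
  expect_warning(out <- minute_ventilation(feats, c(100, 130)))
  expect_equal(out$mv_l_min, 0)
})

test_that("actuation onsets: clean trapezoids, noisy oracle behaviour", {
  fs <- 1000
  spec <- pressure_waveform_spec(20, 0.02, 0.4, 0.3)
  tt <- seq(0, 10, by = 1 / fs)
  p <- command_waveform(spec, tt %% 3)  # cycles at 0, 3, 6, 9
  ev <- detect_actuation_onsets(p, fs, onset_threshold = 1)
  expect_equal(nrow(ev), 4)
  expect_equal(ev$t_P0, c(0.001, 3.001, 6.001, 9.001), tolerance = 2 / fs)
  expect_equal(ev$p_peak, rep(20, 4), tolerance = 1e-6)
  expect_equal(nrow(detect_actuation_onsets(rep(0, 1000), fs)), 0)
  # noise near the threshold must not split a cycle into several events
  set.seed(5)
  pn <- command_waveform(pressure_waveform_spec(20, 0.3, 0.4, 0.3),
                         tt %% 2.5) + rnorm(length(tt), 0, 0.05)
  evn <- detect_actuation_onsets(pn, fs)
  expect_equal(nrow(evn), 4)
})

test_that("breath-actuation matching follows the window rule", {
  feats <- data.frame(t_V0 = c(0, 4, 8), t_Vpk = c(1.5, 5.5, 9.5),
                      Ttot = c(4, 4, 4), TV = c(100, 110, 120),
                      PIF = c(0.3, 0.3, 0.3), Ti = c(1.5, 1.5, 1.5),
                      rr_inst = 15, t_Fpk = c(0.5, 4.5, 8.5))
  ev <- data.frame(t_P0 = c(0.2, 4.2, 8.2), p_peak = 20)
  al <- align_actuations(feats, ev)
  expect_true(all(al$matched))
  expect_equal(al$dt_P0_V0, rep(0.2, 3))
  expect_equal(al$dt_Vpk_P0, rep(1.3, 3))
  # no actuations: all unmatched
  al0 <- align_actuations(feats, ev[0, ])
  expect_true(all(!al0$matched))
  # two actuations inside one breath window: flagged unmatched
  ev2 <- data.frame(t_P0 = c(0.2, 1.0, 4.2, 8.2), p_peak = 20)
  al2 <- align_actuations(feats, ev2)
  expect_false(al2$matched[1])
  expect_true(all(al2$matched[2:3]))
})

test_that("pressure normalization zeroes the breath-bound baseline", {
  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)
  vol <- 100 * (1 - cos(2 * pi * 0.25 * tt))
  segs <- segment_breaths(vol, fs)
  x <- 3 + sin(2 * pi * 0.25 * tt)
  xn <- normalize_pressure(x, segs)
  idx <- unique(c(segs$i_start, segs$i_end[nrow(segs)]))
  expect_lt(abs(mean(xn[idx])), 1e-9 * stats::sd(x))
  # constant series maps to zeros; offsets are invariant
  expect_equal(normalize_pressure(rep(7, length(tt)), segs),
               rep(0, length(tt)))
  expect_equal(normalize_pressure(x + 7, segs), xn)
  expect_warning(normalize_pressure(x, segs[0, ]))
})

test_that("pressure deltas: signed pleural excursion, Pdi on the difference", {
  fs <- 100
  n <- 400
  p_pl <- rep(0, n); p_ab <- rep(0, n)
  p_pl[100:200] <- -8 * sin(seq(0, pi, length.out = 101))
  p_ab[100:200] <- 5 * sin(seq(0, pi, length.out = 101))
  segs <- data.frame(i_start = 50L, i_end = 350L, i_Vpk = 150L, i_Fpk = 100L,
                     t_V0 = 0.49, t_Vpk = 1.49, t_Fpk = 0.99)
  d <- pressure_deltas(segs, p_pl, p_ab)
  expect_equal(d$dPpl, -8)
  expect_equal(d$dPab, 5)
  expect_equal(d$dPdi, 13)  # extrema coincide on the subtracted channel
  z <- pressure_deltas(segs, rep(0, n), rep(0, n))
  expect_equal(unlist(z), c(dPpl = 0, dPab = 0, dPdi = 0))
  expect_error(pressure_deltas(data.frame(i_start = 1L, i_end = 999L,
                                          i_Vpk = 2L), p_pl, p_ab))
})

test_that("timing regression: exact line, null case, normal equations", {
  x <- c(0.1, 0.25, 0.4, 0.55, 0.7)
  fit <- fit_timing_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r2, 1)
  # independent outcome: r2 near zero at n = 200
  set.seed(9)
  xr <- runif(200); yr <- rnorm(200)
  expect_lt(fit_timing_regression(xr, yr)$r2, 0.1)
  # hand-computed normal equations on a 5-point fixture
  xf <- c(1, 2, 3, 4, 5); yf <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  sxx <- sum((xf - mean(xf))^2)
  sxy <- sum((xf - mean(xf)) * (yf - mean(yf)))
  fit2 <- fit_timing_regression(xf, yf)
  expect_equal(fit2$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(fit2$intercept, mean(yf) - sxy / sxx * mean(xf),
               tolerance = 1e-12)
  expect_equal(fit2$n, 5)
  expect_error(fit_timing_regression(c(1, 1, 1), c(1, 2, 3)))
  expect_error(fit_timing_regression(c(1, 2), c(1, 2)))
})
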