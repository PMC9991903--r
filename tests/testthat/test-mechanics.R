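quiet_cfg <- function(...) {
  sim_config(noise = list(flow = 0, p_pl = 0, p_ab = 0, p_act = 0,
                          d_dia = 0, amp = 0), ...)
}

test_that("muscle pressure profile: onset, peak, closed-form relaxation", {
  expect_equal(muscle_pressure(0, 10, 1, 0.2), 0)
  expect_equal(muscle_pressure(1, 10, 1, 0.2), 10)
  expect_equal(muscle_pressure(1.2, 10, 1, 0.2), 10 * exp(-1),
               tolerance = 1e-12)
  ph <- seq(0, 1, by = 0.01)
  expect_true(all(diff(muscle_pressure(ph, 10, 1, 0.2)) >= 0))
  ph2 <- seq(1, 4, by = 0.01)
  expect_true(all(diff(muscle_pressure(ph2, 10, 1, 0.2)) <= 0))
  expect_lt(muscle_pressure(30, 10, 1, 0.2), 1e-12)
  expect_error(muscle_pressure(-0.1, 10, 1, 0.2))
  expect_error(muscle_pressure(0.5, 10, 0, 0.2))
})

test_that("apnoea: no pressure source yields flat channels", {
  cfg <- quiet_cfg(A0 = 0, severed_phrenic = TRUE)
  res <- simulate_subject(cfg, duration = 10)
  expect_true(all(res$record$flow == 0))
  expect_true(all(res$record$volume == 0))
  expect_equal(max(res$record$p_pl) - min(res$record$p_pl), 0)
  # and PaCO2 climbs (hypercarbia under apnoea)
  expect_true(all(diff(res$gas$paco2) > 0))
})

test_that("volume channel equals integrated flow on simulator output", {
  for (nm in c("subject-A", "mech-vent")) {
    res <- run_scenario(nm, 30)
    expect_true(check_flow_volume(res$record, tol = 0.1))
  }
})

test_that("mode sign contracts for pleural and abdominal excursions", {
  # >= 10 steady breaths per arm
  sp <- run_scenario("subject-A", 50, controller = NULL)
  mv <- run_scenario("mech-vent", 50)
  asum <- analyze_record(sp$record)$summary
  msum <- analyze_record(mv$record)$summary
  expect_gt(asum$n_breaths, 10)
  expect_gt(msum$n_breaths, 10)
  expect_lt(asum$mean_dppl, 0)  # spontaneous: negative pleural swing
  expect_gt(msum$mean_dppl, 0)  # MV: positive pleural swing
  expect_gt(asum$mean_dpab, 0)  # diaphragm descent raises P_ab
  expect_lt(abs(msum$mean_dpab), 0.1 * asum$mean_dpab)  # passive diaphragm
  # assisted arm keeps the spontaneous sign pattern
  as <- analyze_record(run_scenario("subject-A", 50)$record)$summary
  expect_lt(as$mean_dppl, 0)
  expect_gt(as$mean_dpab, 0)
})

test_that("severed phrenic removes most of the tidal volume", {
  sc <- scenario_config("severed-phrenic")
  cut <- simulate_subject(sc$config, duration = 60)
  intact_cfg <- sc$config
  intact_cfg$severed_phrenic <- FALSE
  whole <- simulate_subject(intact_cfg, duration = 60)
  tv_cut <- mean(analyze_record(cut$record)$breaths$TV)
  tv_whole <- mean(analyze_record(whole$record)$breaths$TV)
  expect_lt(tv_cut, 0.25 * tv_whole)
})

test_that("noise-free simulation matches a 10x finer-step ODE oracle", {
  # fixed sinusoidal-profile muscle pressure, no assist, no noise
  cfg <- quiet_cfg(A0 = 2, Ti_frac = 0.3, rr_base = 15)
  res <- simulate_subject(cfg, duration = 20)
  C_rs <- 1 / (1 / cfg$C_L + 1 / cfg$C_cw)
  p_fun <- function(t) {
    ph <- (t - 4e-7) %% 4  # breath period 4 s; guard exact-boundary ties
    muscle_pressure(ph, 2, 0.3 * 4, cfg$tau_rel)
  }
  v_ref <- oracle_integrate_eom(p_fun, 20, 1000, 10, cfg$R_aw, C_rs)
  v_sim <- res$record$volume
  segs <- segment_breaths(v_sim, 1000, min_prominence = 2)
  tv_sim <- mean(breath_features(segs, res$record$flow, v_sim, 1000)$TV)
  segs_r <- segment_breaths(v_ref[seq_along(v_sim)], 1000, min_prominence = 2)
  tv_ref <- mean(v_ref[segs_r$i_Vpk] - v_ref[segs_r$i_start])
  expect_lt(abs(tv_sim - tv_ref) / tv_ref, 1e-3)
  # peak pleural excursion agrees as well
  ppl_sim <- min(res$record$p_pl)
  ppl_ref <- min(v_ref[seq_along(v_sim)] / cfg$C_cw -
                   vapply(res$record$t, p_fun, numeric(1)))
  expect_lt(abs(ppl_sim - ppl_ref) / abs(ppl_ref), 1e-3)
})

test_that("identical seeds give bit-identical records", {
  sc <- scenario_config("subject-A")
  r1 <- simulate_subject(sc$config, sc$controller, duration = 15)
  r2 <- simulate_subject(sc$config, sc$controller, duration = 15)
  expect_identical(r1$record$flow, r2$record$flow)
  expect_identical(r1$record$p_pl, r2$record$p_pl)
  expect_identical(r1$triggers, r2$triggers)
  r3 <- simulate_subject(sc$config, sc$controller, duration = 15)
  sc2 <- scenario_config("subject-A", seed = 999)
  r4 <- simulate_subject(sc2$config, sc2$controller, duration = 15)
  expect_false(identical(r3$record$flow, r4$record$flow))
})

test_that("chemoreflex drive raises amplitude and rate under hypercarbia", {
  cfg <- quiet_cfg(A0 = 1.2, G_drive = 0.15, G_rr = 0.4, paco2_set = 40,
                   paco2_0 = 40, rr_base = 16, vco2 = 220, v_store = 4)
  res <- simulate_subject(cfg, duration = 120)
  gt <- res$breaths_gt
  expect_gt(nrow(gt), 20)
  # hypoventilation builds CO2, drive responds: later breaths are deeper and
  # faster than the first ones
  early <- gt[gt$t_start < 20, ]
  late <- gt[gt$t_start > 90, ]
  expect_gt(mean(late$amplitude), mean(early$amplitude))
  expect_lt(mean(late$period), mean(early$period))
  expect_gt(res$gas$paco2[nrow(res$gas)], res$gas$paco2[1])
})

test_that("simulator rejects invalid drive combinations and durations", {
  cfg <- sim_config()
  expect_error(simulate_subject(cfg, duration = -1))
  expect_error(simulate_subject(cfg, duration = 1))  # under one breath period
  expect_error(simulate_subject(sim_config(A0 = 2),
                                ventilator = ventilator_settings(),
                                duration = 30))
  expect_error(sim_config(R_aw = -1))
  expect_error(sim_config(Ti_frac = 1.2))
  expect_error(sim_config(A0 = NaN))
  expect_error(sim_config(f_di = 1.4))
})

test_that("ventilated subject: positive pleural swing, near-passive abdomen", {
  mv <- run_scenario("mech-vent", 40)
  a <- analyze_record(mv$record)
  expect_gt(a$summary$n_breaths, 8)
  expect_gt(a$summary$mean_dppl, 0)
  expect_gt(a$summary$mean_tv_ml, 150)  # physiological MV tidal volume
})
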