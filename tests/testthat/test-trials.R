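test_that("ramp schedule step function follows the protocol convention", {
  sch <- ramp_schedule("P_crit", fixed_value = 36, start_value = 20)
  expect_equal(env_at(sch, 0), 20)
  expect_equal(env_at(sch, 29), 20)    # still equilibrating
  expect_equal(env_at(sch, 30), 20)    # step takes effect just after 30
  expect_equal(env_at(sch, 30.5), 21)
  expect_equal(env_at(sch, 36), 22)
  sch_t <- ramp_schedule("T_crit", fixed_value = 16, start_value = 36)
  expect_equal(env_at(sch_t, 100), 50)
  expect_error(ramp_schedule("P_crit", 36, 20, step = 0), "positive")
})

test_that("last completed stage tracks full intervals only", {
  sch <- ramp_schedule("P_crit", 36, 20)
  expect_equal(last_completed_stage(sch, 29), 20)
  expect_equal(last_completed_stage(sch, 34.9), 20)
  expect_equal(last_completed_stage(sch, 35), 21)
  expect_equal(last_completed_stage(sch, 125), 39)
})

test_that("heat-balance estimate solves the compensability boundary", {
  hb <- heat_balance_params()  # t_sk 36, h_c 4.3, h_r 4.7, w_max 0.65
  # hand-evaluated: E_req = 80 - 9*2 = 62; P_sat(36) - 62/(0.65*9.46)
  expected <- saturation_vapor_pressure(36) - 62 / (0.65 * 2.2 * 4.3)
  expect_equal(estimate_censored_limit(80, 34, last_stage = 20, hb = hb,
                                       clamp = 50), expected)
  # wildly negative raw estimates clamp to the last completed stage
  hb2 <- heat_balance_params(h_e = 0.42, w_max = 1)
  raw <- saturation_vapor_pressure(36) - (48 - 9 * 2) / 0.42
  expect_lt(raw, 0)
  expect_equal(estimate_censored_limit(48, 34, last_stage = 28, hb = hb2), 28)
  # estimates never exceed last stage + 5 (the protocol-anchored clamp)
  for (m in seq(40, 120, by = 20)) {
    est <- estimate_censored_limit(m, 34, last_stage = 28)
    expect_gte(est, 28)
    expect_lte(est, 33)
  }
  # zero (or negative) required evaporation returns the clamp upper bound
  expect_warning(up <- estimate_censored_limit(10, 34, last_stage = 28),
                 "negative")
  expect_equal(up, 33)
})

test_that("heat-balance estimate is monotone in M_net and T_db", {
  wide <- 1e6  # push both clamp bounds out of the way
  ms <- seq(40, 100, by = 10)
  est_m <- vapply(ms, estimate_censored_limit, numeric(1), t_db = 34,
                  last_stage = -1e3, clamp = wide)
  expect_true(all(diff(est_m) < 0))
  # warmer air at fixed skin temperature reduces dry heat loss, raising the
  # evaporative requirement: the tolerable vapor pressure falls with T_db
  ts <- seq(30, 36, by = 1)
  est_t <- vapply(ts, function(td) estimate_censored_limit(80, td,
                  last_stage = -1e3, clamp = wide), numeric(1))
  expect_true(all(diff(est_t) < 0))
})

test_that("analyze_trial recovers a constructed critical vapor pressure", {
  sch <- ramp_schedule("P_crit", fixed_value = 40, start_value = 20)
  tr <- generate_trace(trace_spec(sch, true_critical = 29, noise_sd = 0.05,
                                  ar1 = 0.8, seed = 4))
  rec <- trial_record("t1", test_subject(), "Rest", sch, tr,
                      vo2 = c(0.27, 0.28), rer = 0.85,
                      mass_pre = 73.4, mass_post = 73.2)
  res <- suppressMessages(analyze_trial(rec))
  expect_false(res$censored)
  # single noisy trace: within two ramp steps (breakpoint localization under
  # AR(1) noise has a known few-minute spread; the aggregate rate is tested
  # in the acceptance suite)
  expect_lte(abs(res$critical_value - 29), 2)
  # axis roles: P_crit locus is (fixed T_db, critical P_a)
  expect_equal(res$t_db, 40)
  expect_equal(res$p_a, res$critical_value)
  expect_gt(res$rh, 0)
  expect_lte(res$rh, 100)
  expect_gt(res$m_net, 40)
  expect_gt(res$sr, 0)
})

test_that("trials without an inflection are censored at the last stage", {
  sch <- ramp_schedule("P_crit", fixed_value = 36, start_value = 14)
  tr <- generate_trace(trace_spec(sch, true_critical = Inf, noise_sd = 0.05,
                                  ar1 = 0.8, seed = 9))
  rec <- trial_record("t2", test_subject(), "MinAct", sch, tr)
  res <- analyze_trial(rec)
  expect_true(res$censored)
  expect_equal(res$estimation, "observed")
  expect_equal(res$critical_value, last_completed_stage(sch, max(tr$t)))
})

test_that("censored 34-degree humidity trials route to heat-balance estimation", {
  sch <- ramp_schedule("P_crit", fixed_value = 34, start_value = 16)
  tr <- generate_trace(trace_spec(sch, true_critical = Inf, noise_sd = 0.05,
                                  ar1 = 0.8, seed = 10))
  rec <- trial_record("t3", test_subject(), "Rest", sch, tr,
                      vo2 = c(0.27, 0.28), rer = 0.85)
  res <- analyze_trial(rec)
  expect_false(res$censored)
  expect_equal(res$estimation, "heat_balance_estimated")
  last <- last_completed_stage(sch, max(tr$t))
  expect_gte(res$critical_value, last)
  expect_lte(res$critical_value, last + 5)
  # without metabolic data the same trial stays censored
  rec2 <- trial_record("t4", test_subject(), "Rest", sch, tr)
  expect_true(analyze_trial(rec2)$censored)
})

test_that("T_crit locus keeps the vapor-pressure axis fixed", {
  sch <- ramp_schedule("T_crit", fixed_value = 16, start_value = 36)
  tr <- generate_trace(trace_spec(sch, true_critical = 44, noise_sd = 0.05,
                                  ar1 = 0.8, seed = 12))
  rec <- trial_record("t5", test_subject(), "MinAct", sch, tr)
  res <- analyze_trial(rec)
  expect_equal(res$p_a, 16)
  expect_equal(res$t_db, res$critical_value)
  expect_lte(abs(res$critical_value - 44), 1.5)
})

test_that("batches preserve order and tolerate individual failures", {
  sch <- ramp_schedule("P_crit", 40, 20)
  recs <- lapply(1:3, function(i) {
    tr <- generate_trace(trace_spec(sch, 29, noise_sd = 0.03, ar1 = 0.5,
                                    seed = i))
    trial_record(paste0("tr", i), test_subject(), "MinAct", sch, tr)
  })
  res <- analyze_trials(recs)
  expect_equal(res$trial_id, c("tr1", "tr2", "tr3"))
  # a too-short trace is rejected with a warning, others still analyzed
  short <- hl_trace(0:40, rep(37, 41), env_at(sch, 0:40), 40)
  recs[[2]] <- trial_record("bad", test_subject(), "MinAct", sch, short)
  expect_warning(res2 <- analyze_trials(recs), "excluded")
  expect_equal(res2$trial_id, c("tr1", "tr3"))
})
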