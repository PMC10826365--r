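test_that("trace constructor enforces its invariants", {
  expect_error(hl_trace(1:3, c(37, 37), rep(20, 3), 40), "equal length")
  expect_error(hl_trace(c(1, 2, 2), rep(37, 3), rep(20, 3), 40),
               "strictly increasing")
  expect_error(hl_trace(c(1, 2, 4), rep(37, 3), rep(20, 3), 40),
               "spacing")
  expect_error(hl_trace(1:3, c(37, NA, 37), rep(20, 3), 40), "missing")
  expect_warning(hl_trace(1:3, c(37, 42, 37), rep(20, 3), 40),
                 "physiological screen")
})

test_that("noise-free piecewise-linear trace is recovered exactly", {
  tr <- flat_rise_trace(flat_min = 60, total = 100, rise_per_h = 0.7)
  fit <- detect_inflection(tr)
  expect_true(fit$detected)
  expect_lte(abs(fit$breakpoint_time - 60), 1)
  expect_equal(fit$slope_below, 0, tolerance = 1e-6)
  expect_equal(fit$slope_above, 0.7, tolerance = 1e-6)
})

test_that("no inflection is declared on featureless traces", {
  sch <- ramp_schedule("P_crit", 40, 20)
  t <- 0:100
  # strictly linear rise throughout: no slope change exists
  lin <- hl_trace(t, 37 + 0.005 * t, env_at(sch, t), 40)
  expect_false(detect_inflection(lin)$detected)
  # all-constant core temperature
  flat <- hl_trace(t, rep(37, 101), env_at(sch, t), 40)
  expect_false(detect_inflection(flat)$detected)
  # too-short trace is a protocol error
  short <- hl_trace(0:50, rep(37, 51), env_at(sch, 0:50), 40)
  expect_error(detect_inflection(short), "need at least")
})

test_that("detector SSE is minimal over candidates (independent grid check)", {
  # independent re-implementation with lm() on the same grid, plain OLS
  tr <- flat_rise_trace(flat_min = 70, total = 110, rise_per_h = 0.6,
                        noise_sd = 0.04, seed = 21)
  fit <- detect_inflection(tr, ar_correction = FALSE, slope_prior = NULL)
  keep <- tr$t >= 45
  tt <- tr$t[keep]
  y <- tr$t_gi[keep]
  cands <- tt[tt <= max(tt) - 10]
  cands <- cands[vapply(cands, function(b)
    sum(tt < b) >= 2 && sum(tt > b) >= 2, logical(1))]
  sses <- vapply(cands, function(b) {
    sum(resid(lm(y ~ tt + pmax(tt - b, 0)))^2)
  }, numeric(1))
  expect_equal(fit$sse, min(sses), tolerance = 1e-10)
  expect_equal(fit$breakpoint_time, cands[which.min(sses)])
})

test_that("white-noise recovery holds at the constructed-trace benchmark", {
  hits <- 0
  for (s in 1:60) {
    tr <- flat_rise_trace(flat_min = 60, total = 100, rise_per_h = 0.7,
                          noise_sd = 0.05, seed = s)
    fit <- detect_inflection(tr, search_start = 0)
    if (fit$detected && abs(fit$breakpoint_time - 60) <= 5) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.9)
})

test_that("breakpoint RMSE is non-decreasing in noise level", {
  rmse <- vapply(c(0.01, 0.05, 0.1), function(sig) {
    errs <- vapply(1:40, function(s) {
      tr <- flat_rise_trace(flat_min = 60, total = 100, rise_per_h = 0.7,
                            noise_sd = sig, seed = s)
      fit <- detect_inflection(tr, search_start = 0)
      if (fit$detected) fit$breakpoint_time - 60 else NA_real_
    }, numeric(1))
    sqrt(mean(errs^2, na.rm = TRUE))
  }, numeric(1))
  expect_true(all(diff(rmse) >= 0))
})

test_that("every detected fit has slope_above greater than slope_below", {
  sch <- ramp_schedule("P_crit", 40, 20)
  for (s in 1:25) {
    tr <- generate_trace(trace_spec(sch, 29, noise_sd = 0.05, ar1 = 0.8,
                                    seed = s))
    fit <- detect_inflection(tr)
    if (fit$detected) expect_gt(fit$slope_above, fit$slope_below)
  }
})

test_that("critical value averages the 2 min preceding the inflection", {
  sch <- ramp_schedule("P_crit", 40, 20)
  tr <- flat_rise_trace(flat_min = 60, total = 100)
  fit <- detect_inflection(tr)
  # full window inside one step: value equals that step
  expect_equal(critical_env_value(tr, fit),
               env_at(sch, fit$breakpoint_time - 1))
  # constant environment in the window
  tr2 <- hl_trace(0:100, tr$t_gi, rep(16, 101), 40)
  expect_equal(critical_env_value(tr2, fit), 16)
  # window straddling a step boundary averages the two stages
  env <- c(rep(28, 59), rep(29, 42))  # step at t = 59, 1 min before bp
  tr3 <- hl_trace(0:100, tr$t_gi, env, 40)
  fit60 <- fit
  fit60$breakpoint_time <- 60
  expect_equal(critical_env_value(tr3, fit60), 28.5)
  expect_error(critical_env_value(tr, list(detected = FALSE)),
               "hl_inflection")
})

test_that("rate of change recovers noise-free slopes and handles short spans", {
  tr <- flat_rise_trace(flat_min = 60, total = 100, rise_per_h = 0.7)
  mu <- 37 + 0.1 / 60 * tr$t + 0.6 / 60 * pmax(0, tr$t - 60)
  tr2 <- hl_trace(tr$t, mu, tr$env, 40)
  fit <- detect_inflection(tr2)
  sl <- tgi_rate_of_change(tr2, fit)
  expect_equal(sl$below, 0.1, tolerance = 1e-6)
  expect_equal(sl$above, 0.7, tolerance = 1e-6)
  # two points in the window define the slope exactly
  fit2 <- fit
  fit2$breakpoint_time <- 60
  sl2 <- tgi_rate_of_change(tr2, fit2, window = 2, guard = 0)
  expect_equal(sl2$below, 0.1, tolerance = 1e-6)
  # post-breakpoint span shorter than window falls back to available span
  fit3 <- fit
  fit3$breakpoint_time <- 90
  sl3 <- tgi_rate_of_change(tr2, fit3, window = 20, guard = 0)
  expect_equal(sl3$above, 0.7, tolerance = 1e-6)
  fit4 <- fit
  fit4$breakpoint_time <- 98
  expect_error(tgi_rate_of_change(tr2, fit4), "after the breakpoint")
})
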