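make_results <- function(p_a, t_db = 36, mode = "P_crit", condition = 36,
                         age_group = "older", activity = "MinAct",
                         censored = FALSE) {
  n <- length(p_a)
  data.frame(age_group = age_group, activity = activity, mode = mode,
             condition = condition, t_db = t_db, p_a = p_a,
             rh = relative_humidity(rep_len(t_db, n), p_a,
                                    allow_supersaturation = TRUE),
             critical_value = if (mode == "P_crit") p_a else t_db,
             censored = rep_len(censored, n), stringsAsFactors = FALSE)
}

test_that("locus aggregation computes t-based intervals", {
  # identical trials: zero-width interval
  r <- make_results(rep(25, 4))
  agg <- aggregate_loci(r)
  expect_equal(agg$p_a, 25)
  expect_equal(agg$p_a_lo, 25)
  expect_equal(agg$p_a_hi, 25)
  # hand t-interval: {23, 25, 27} -> 25 +/- qt(.975, 2) * 2/sqrt(3)
  agg2 <- aggregate_loci(make_results(c(23, 25, 27)))
  half <- qt(0.975, 2) * sd(c(23, 25, 27)) / sqrt(3)
  expect_equal(agg2$p_a, 25)
  expect_equal(agg2$p_a_hi - agg2$p_a, half, tolerance = 1e-10)
  expect_equal(half, 4.968, tolerance = 1e-3)
  # singleton cell: mean kept, interval flagged unavailable
  agg3 <- aggregate_loci(make_results(25))
  expect_true(is.na(agg3$p_a_lo))
  # censored trials are excluded from the means
  r4 <- make_results(c(23, 25, 27, 40), censored = c(rep(FALSE, 3), TRUE))
  expect_equal(aggregate_loci(r4)$p_a, 25)
  expect_equal(aggregate_loci(r4, drop_censored = FALSE)$p_a, 28.75)
})

test_that("quadratic limit curve: exact interpolation and recovery", {
  # three points define the parabola exactly
  pts <- data.frame(t_db = c(34, 38, 42), p_a = c(26, 23, 12))
  cv <- fit_psychrometric_curve(pts)
  expect_equal(max(abs(cv$residuals)), 0, tolerance = 1e-10)
  expect_equal(predict(cv, c(34, 38, 42)), pts$p_a, tolerance = 1e-10)
  # jittered parabola: coefficients recovered within noise-scaled tolerance
  set.seed(17)
  t_db <- seq(34, 46, by = 2)
  truth <- c(120, -3.4, 0.015)
  y <- truth[1] + truth[2] * t_db + truth[3] * t_db^2 + rnorm(7, 0, 0.05)
  cv2 <- fit_psychrometric_curve(data.frame(t_db = t_db, p_a = y))
  expect_equal(predict(cv2, seq(34, 46, 1)),
               truth[1] + truth[2] * seq(34, 46, 1) +
                 truth[3] * seq(34, 46, 1)^2,
               tolerance = 0.01)
  expect_error(fit_psychrometric_curve(pts[1:2, ]), "3 distinct")
  expect_error(predict(cv, 50), "extrapolation")
})

test_that("reference mean curves: older minimal-activity curve lies lowest", {
  ref <- reference_critical_loci()
  fit_grp <- function(g) fit_psychrometric_curve(ref[ref$group == g, ])
  om <- fit_grp("older-MinAct")
  ym <- fit_grp("young-MinAct")
  or <- fit_grp("older-Rest")
  grid <- seq(34, 41, by = 0.25)
  expect_true(all(predict(om, grid) < predict(ym, grid, extrapolate = 2)))
  expect_true(all(predict(om, grid) < predict(or, grid, extrapolate = 2)))
})

test_that("lower-CI curve sits below the mean curve across its span", {
  ref <- reference_critical_loci()
  om <- ref[ref$group == "older-MinAct", ]
  mean_cv <- fit_psychrometric_curve(om, variant = "mean")
  low_cv <- fit_psychrometric_curve(om, variant = "lower95")
  grid <- seq(34, 41, by = 0.5)
  expect_true(all(predict(low_cv, grid, extrapolate = 2) <
                    predict(mean_cv, grid)))
})

test_that("compensability classification is consistent and order-invariant", {
  ref <- reference_critical_loci()
  om <- ref[ref$group == "older-MinAct", ]
  cv <- fit_psychrometric_curve(om)
  shuffled <- fit_psychrometric_curve(om[sample(nrow(om)), ])
  expect_equal(cv$coef, shuffled$coef)
  grid <- seq(35, 41, by = 1)
  on_curve <- predict(cv, grid)
  expect_true(all(is_compensable(cv, grid, on_curve - 0.5)))
  expect_true(all(!is_compensable(cv, grid, on_curve + 0.5)))
})

test_that("permutation comparison: null identity and offset power", {
  a <- do.call(rbind, lapply(c(34, 36, 38), function(cond)
    make_results(c(23, 24, 25, 26), condition = cond)))
  p_null <- compare_limit_sets(a, a, n_perm = 199, seed = 1)$p
  expect_gte(p_null, 0.9)
  b <- a
  b$critical_value <- b$critical_value + 6
  expect_lte(compare_limit_sets(a, b, n_perm = 199, seed = 1)$p, 0.01)
  expect_error(compare_limit_sets(a[a$condition == 34, ],
                                  b[b$condition == 34, ]), "2 conditions")
})

test_that("permutation comparison has calibrated type-I error", {
  set.seed(18)
  rej <- 0
  n_sim <- 400
  for (i in 1:n_sim) {
    a <- do.call(rbind, lapply(c(34, 36), function(cond)
      make_results(rnorm(6, 25, 3), condition = cond)))
    b <- do.call(rbind, lapply(c(34, 36), function(cond)
      make_results(rnorm(6, 25, 3), condition = cond)))
    if (compare_limit_sets(a, b, n_perm = 99)$p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_sim, 0.02)
  expect_lte(rej / n_sim, 0.08)
})
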