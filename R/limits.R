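#' Aggregate per-trial loci into condition-level critical limits
#'
#' Per condition-group cell: mean and t-based 95% CI of the dry-bulb
#' temperature, vapor pressure, and relative humidity at the critical limit.
#' Relative humidity is averaged as the mean of per-trial ratios (matching
#' how summary tables report it), not recomputed from the mean temperature
#' and pressure — the two differ because rh is nonlinear in (T_db, P_a).
#' Cells with a single trial report the mean with `NA` CI bounds.
#'
#' Trials censored without an estimated limit carry only a lower bound on
#' the critical value, so they are excluded from locus means by default
#' (heat-balance-estimated trials, which are not censored, are included).
#'
#' @param results Trial-results data.frame from [analyze_trials()] (needs
#'   columns `t_db`, `p_a`, `rh`, `mode`, `condition` plus the grouping
#'   columns).
#' @param grouping Character vector of column names defining the group (in
#'   addition to mode and condition); default `c("age_group", "activity")`.
#' @param conf_level Confidence level (default 0.95).
#' @param drop_censored Exclude censored (bound-only) trials (default TRUE).
#' @return Data.frame with one row per cell: grouping columns, `mode`,
#'   `condition`, `n`, `n_censored` (excluded trials), and for each of
#'   `t_db`, `p_a`, `rh` the mean and `_lo`/`_hi` CI bounds.
#' @export
aggregate_loci <- function(results, grouping = c("age_group", "activity"),
                           conf_level = 0.95, drop_censored = TRUE) {
  stopifnot(is.data.frame(results))
  n_cens_all <- 0L
  if (drop_censored && "censored" %in% names(results)) {
    n_cens_all <- sum(results$censored)
    results <- results[!results$censored, , drop = FALSE]
  }
  keys <- c(grouping, "mode", "condition")
  if (!all(keys %in% names(results))) {
    stop("results lacks grouping columns: ",
         paste(setdiff(keys, names(results)), collapse = ", "), call. = FALSE)
  }
  split_idx <- split(seq_len(nrow(results)),
                     results[keys], drop = TRUE, sep = "\r")
  ci <- function(x) {
    m <- mean(x)
    n <- length(x)
    if (n < 2) return(c(mean = m, lo = NA_real_, hi = NA_real_))
    half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * stats::sd(x) / sqrt(n)
    c(mean = m, lo = m - half, hi = m + half)
  }
  rows <- lapply(split_idx, function(idx) {
    cell <- results[idx, , drop = FALSE]
    out <- cell[1, keys, drop = FALSE]
    out$n <- length(idx)
    out$n_censored <- if ("censored" %in% names(cell)) sum(cell$censored) else 0L
    for (v in c("t_db", "p_a", "rh")) {
      est <- ci(cell[[v]])
      out[[v]] <- est[["mean"]]
      out[[paste0(v, "_lo")]] <- est[["lo"]]
      out[[paste0(v, "_hi")]] <- est[["hi"]]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a quadratic psychrometric limit curve
#'
#' Second-order least-squares polynomial P_a = a T_db^2 + b T_db + c through
#' condition-level critical loci, the standard construction for critical
#' environmental limit lines on a psychrometric chart. The `variant` selects
#' which locus summary is fit: cell means, or the lower 95% CI bounds of the
#' ramped variable (the conservative boundary drawn on published charts).
#'
#' @param loci Data.frame from [aggregate_loci()], or any data.frame with
#'   columns `t_db`, `p_a` (+ `_lo` columns for the `lower95` variant and
#'   `mode` to know which axis was ramped).
#' @param variant `"mean"` or `"lower95"`.
#' @return Object of class `hl_limit_curve`: list with `coef` (c, b, a — as
#'   returned for powers 0..2), `span` (fitted T_db range), `variant`,
#'   `residuals`, `points`.
#' @export
fit_psychrometric_curve <- function(loci, variant = c("mean", "lower95")) {
  variant <- match.arg(variant)
  if (variant == "mean") {
    x <- loci$t_db
    y <- loci$p_a
  } else {
    if (!all(c("t_db_lo", "p_a_lo", "mode") %in% names(loci))) {
      stop("lower95 variant needs t_db_lo, p_a_lo and mode columns",
           call. = FALSE)
    }
    # conservative bound: lower CI of whichever variable was ramped
    ramped_p <- loci$mode == "P_crit"
    x <- ifelse(ramped_p, loci$t_db, loci$t_db_lo)
    y <- ifelse(ramped_p, loci$p_a_lo, loci$p_a)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(unique(x)) < 3) {
    stop("need at least 3 distinct t_db values to fit a quadratic",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x + I(x^2))
  structure(list(coef = unname(stats::coef(fit)), span = range(x),
                 variant = variant, residuals = unname(stats::resid(fit)),
                 points = data.frame(t_db = x, p_a = y)),
            class = "hl_limit_curve")
}

#' Evaluate a fitted limit curve
#'
#' @param object An `hl_limit_curve`.
#' @param t_db Dry-bulb temperatures at which to evaluate, degC. Must lie
#'   within the fitted span extended by at most `extrapolate` degC.
#' @param extrapolate Permitted extrapolation beyond the fitted span, degC
#'   (default 1).
#' @param ... Unused.
#' @return Predicted vapor pressure, mmHg.
#' @export
predict.hl_limit_curve <- function(object, t_db, extrapolate = 1, ...) {
  lo <- object$span[1] - extrapolate
  hi <- object$span[2] + extrapolate
  if (any(t_db < lo | t_db > hi)) {
    stop("t_db outside fitted span [", round(lo, 1), ", ", round(hi, 1),
         "]; extrapolation refused", call. = FALSE)
  }
  cf <- object$coef
  cf[1] + cf[2] * t_db + cf[3] * t_db^2
}

#' @export
print.hl_limit_curve <- function(x, ...) {
  cat(sprintf(
    "<limit curve (%s)> P_a = %.4g + %.4g T + %.4g T^2 on [%.1f, %.1f] degC\n",
    x$variant, x$coef[1], x$coef[2], x$coef[3], x$span[1], x$span[2]))
  invisible(x)
}

#' Classify a point against a limit curve
#'
#' A (T_db, P_a) point below the curve is compensable; above, uncompensable.
#'
#' @inheritParams predict.hl_limit_curve
#' @param curve An `hl_limit_curve`.
#' @param p_a Vapor pressure(s), mmHg.
#' @return Logical: `TRUE` where compensable.
#' @export
is_compensable <- function(curve, t_db, p_a, extrapolate = 1) {
  p_a < predict(curve, t_db, extrapolate = extrapolate)
}

#' Permutation comparison of two groups' critical limits
#'
#' Within-condition label-permutation test replacing a mixed-effects model:
#' the test statistic is the mean (over shared conditions) of the difference
#' in group mean critical values; group labels are permuted within each
#' condition, and the two-sided Monte-Carlo p-value uses the add-one
#' correction.
#'
#' @param results_a,results_b Trial-results data.frames (columns
#'   `condition`, `mode`, `critical_value`).
#' @param n_perm Number of Monte-Carlo permutations (default 999).
#' @param seed Optional RNG seed.
#' @return List with `p`, `statistic` (mean signed difference, A minus B),
#'   `n_perm`, `conditions`.
#' @export
compare_limit_sets <- function(results_a, results_b, n_perm = 999,
                               seed = NULL) {
  key_a <- paste(results_a$mode, results_a$condition)
  key_b <- paste(results_b$mode, results_b$condition)
  shared <- intersect(unique(key_a), unique(key_b))
  if (length(shared) < 2) {
    stop("need at least 2 conditions shared between groups", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  stat <- function(val_a, val_b, keys_a, keys_b) {
    mean(vapply(shared, function(k) {
      mean(val_a[keys_a == k]) - mean(val_b[keys_b == k])
    }, numeric(1)))
  }
  obs <- stat(results_a$critical_value, results_b$critical_value, key_a, key_b)
  pooled_val <- c(results_a$critical_value, results_b$critical_value)
  pooled_key <- c(key_a, key_b)
  is_a <- rep(c(TRUE, FALSE), c(nrow(results_a), nrow(results_b)))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm_a <- logical(length(pooled_val))
    for (k in shared) {
      idx <- which(pooled_key == k)
      perm_a[sample(idx, sum(is_a[idx]))] <- TRUE
    }
    s <- stat(pooled_val[perm_a], pooled_val[!perm_a],
              pooled_key[perm_a], pooled_key[!perm_a])
    if (abs(s) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  list(p = (hits + 1) / (n_perm + 1), statistic = obs, n_perm = n_perm,
       conditions = shared)
}
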