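#' Compensability curve (product-limit estimator)
#'
#' Survival-style step function of the percentage of subjects for whom heat
#' stress is still compensable as environmental stress (vapor pressure or
#' dry-bulb temperature) increases — the Kaplan-Meier product-limit estimator
#' with stress replacing time. Right-censored observations (still compensable
#' at the last observed stress) reduce the risk set without stepping the
#' curve down; all events tied at one stress are handled in a single
#' risk-set step, which matters because step protocols quantize stresses to
#' integers.
#'
#' @param stress Numeric vector of stress values at which heat stress became
#'   uncompensable (events) or observation ended (censored).
#' @param censored Logical vector, `TRUE` where the subject was still
#'   compensable at `stress` (right-censored). Default all `FALSE`.
#' @return Object of class `hl_comp_curve`: a data.frame with one row per
#'   distinct stress value carrying `stress`, `n_risk`, `n_event`,
#'   `n_censor`, and `surv_pct` (percent still compensable after that
#'   stress). The curve starts implicitly at 100%.
#' @export
compensability_curve <- function(stress, censored = rep(FALSE, length(stress))) {
  if (!length(stress)) stop("need at least one observation", call. = FALSE)
  if (length(censored) != length(stress)) {
    stop("stress and censored must have equal length", call. = FALSE)
  }
  if (any(stress <= 0)) stop("stress values must be positive", call. = FALSE)
  o <- order(stress)
  stress <- stress[o]
  censored <- censored[o]
  s_vals <- sort(unique(stress))
  n <- length(stress)
  surv <- 1
  rows <- lapply(s_vals, function(s) {
    at_risk <- sum(stress >= s)
    d <- sum(stress == s & !censored)
    c_ <- sum(stress == s & censored)
    if (d > 0) surv <<- surv * (1 - d / at_risk)
    data.frame(stress = s, n_risk = at_risk, n_event = d, n_censor = c_,
               surv_pct = 100 * surv)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("hl_comp_curve", "data.frame"), n = n)
}

# per-stress risk/event table for a two-group comparison
.two_group_table <- function(stress_a, cens_a, stress_b, cens_b) {
  stress <- c(stress_a, stress_b)
  cens <- c(cens_a, cens_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(stress_a), length(stress_b)))
  s_vals <- sort(unique(stress[!cens]))
  do.call(rbind, lapply(s_vals, function(s) {
    n_i <- sum(stress >= s)
    n_ai <- sum(stress >= s & grp_a)
    d_i <- sum(stress == s & !cens)
    d_ai <- sum(stress == s & !cens & grp_a)
    data.frame(stress = s, n = n_i, n_a = n_ai, d = d_i, d_a = d_ai)
  }))
}

#' Gehan-Breslow-Wilcoxon test
#'
#' Weighted log-rank test for a difference between two compensability
#' (survival) curves, with weight w_i = n_i (total number at risk) at each
#' distinct event stress — the Gehan-Breslow generalization of the Wilcoxon
#' test, which emphasizes differences at low stress where many subjects are
#' still at risk. The statistic is
#' U = sum w_i (d_Ai - n_Ai d_i / n_i) with variance
#' V = sum w_i^2 d_i (n_i - d_i) n_Ai (n_i - n_Ai) / (n_i^2 (n_i - 1)),
#' and chi2 = U^2 / V is referred to a chi-square with 1 df (two-sided).
#' With `weights = "logrank"` all weights are 1 and the statistic reduces to
#' the standard log-rank test.
#'
#' @param stress_a,stress_b Stress values for the two groups.
#' @param cens_a,cens_b Logical censoring indicators (default none censored).
#' @param weights `"gehan"` (default, w_i = n_i) or `"logrank"` (w_i = 1).
#' @return List with `u` (weighted score), `chi2`, `p` (two-sided), and the
#'   per-stress table used.
#' @export
gehan_breslow_wilcoxon <- function(stress_a, stress_b,
                                   cens_a = rep(FALSE, length(stress_a)),
                                   cens_b = rep(FALSE, length(stress_b)),
                                   weights = c("gehan", "logrank")) {
  weights <- match.arg(weights)
  if (!length(stress_a) || !length(stress_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (all(cens_a) && all(cens_b)) {
    stop("no uncensored events in either group; test undefined",
         call. = FALSE)
  }
  tab <- .two_group_table(stress_a, cens_a, stress_b, cens_b)
  w <- if (weights == "gehan") tab$n else rep(1, nrow(tab))
  u <- sum(w * (tab$d_a - tab$n_a * tab$d / tab$n))
  vterm <- ifelse(tab$n > 1,
                  tab$d * (tab$n - tab$d) * tab$n_a * (tab$n - tab$n_a) /
                    (tab$n^2 * (tab$n - 1)),
                  0)
  v <- sum(w^2 * vterm)
  chi2 <- if (v > 0) u^2 / v else 0
  p <- if (v > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  list(u = u, v = v, chi2 = chi2, p = p, table = tab, weights = weights)
}

#' Stratified Gehan-Breslow-Wilcoxon test
#'
#' Combines per-stratum (e.g. per environmental condition) two-group
#' comparisons into one chi-square statistic by summing the weighted scores
#' and their variances across strata, exactly as the stratified log-rank
#' test does. This is the package's aggregate test of "group A's
#' compensability curves sit left of group B's across all conditions"; it
#' never compares stresses from different strata (and so never mixes the
#' vapor-pressure and dry-bulb axes).
#'
#' @param stress_a,stress_b Stress values for the two groups.
#' @param strata_a,strata_b Stratum labels, parallel to the stress vectors.
#' @param cens_a,cens_b Logical censoring indicators.
#' @inheritParams gehan_breslow_wilcoxon
#' @return List with `u`, `v`, `chi2`, `p`, and the per-stratum test list.
#' @export
gbw_stratified <- function(stress_a, stress_b, strata_a, strata_b,
                           cens_a = rep(FALSE, length(stress_a)),
                           cens_b = rep(FALSE, length(stress_b)),
                           weights = c("gehan", "logrank")) {
  weights <- match.arg(weights)
  strata <- union(unique(strata_a), unique(strata_b))
  per <- lapply(stats::setNames(strata, strata), function(k) {
    ia <- strata_a == k
    ib <- strata_b == k
    if (!any(ia) || !any(ib)) return(NULL)
    if (all(cens_a[ia]) && all(cens_b[ib])) return(NULL)
    gehan_breslow_wilcoxon(stress_a[ia], stress_b[ib],
                           cens_a[ia], cens_b[ib], weights)
  })
  per <- Filter(Negate(is.null), per)
  if (!length(per)) stop("no stratum with events in both groups", call. = FALSE)
  u <- sum(vapply(per, `[[`, numeric(1), "u"))
  v <- sum(vapply(per, `[[`, numeric(1), "v"))
  chi2 <- if (v > 0) u^2 / v else 0
  p <- if (v > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  list(u = u, v = v, chi2 = chi2, p = p, strata = per)
}

#' Permutation p-value for the Gehan-Breslow-Wilcoxon statistic
#'
#' Reference implementation used as an independent oracle for the chi-square
#' approximation: the group labels are permuted, holding the pooled
#' (stress, censored) observations fixed, and the two-sided p-value is the
#' fraction of label assignments whose chi-square statistic is at least the
#' observed one. Exact enumeration of all assignments is used when their
#' number is at most `max_exact`; otherwise `n_mc` Monte-Carlo draws with a
#' `+1` correction.
#'
#' @inheritParams gehan_breslow_wilcoxon
#' @param max_exact Enumeration cap on `choose(n, n_a)`.
#' @param n_mc Monte-Carlo permutation count when enumeration is infeasible.
#' @param seed Optional RNG seed for the Monte-Carlo branch.
#' @return List with `p`, `exact` (logical), and `n_perm`.
#' @export
gbw_permutation_p <- function(stress_a, stress_b,
                              cens_a = rep(FALSE, length(stress_a)),
                              cens_b = rep(FALSE, length(stress_b)),
                              weights = c("gehan", "logrank"),
                              max_exact = 20000, n_mc = 2000, seed = NULL) {
  weights <- match.arg(weights)
  obs <- gehan_breslow_wilcoxon(stress_a, stress_b, cens_a, cens_b, weights)
  stress <- c(stress_a, stress_b)
  cens <- c(cens_a, cens_b)
  n <- length(stress)
  n_a <- length(stress_a)
  stat_for <- function(idx_a) {
    gehan_breslow_wilcoxon(stress[idx_a], stress[-idx_a],
                           cens[idx_a], cens[-idx_a], weights)$chi2
  }
  if (choose(n, n_a) <= max_exact) {
    combos <- utils::combn(n, n_a)
    stats_all <- apply(combos, 2, stat_for)
    p <- mean(stats_all >= obs$chi2 - 1e-12)
    list(p = p, exact = TRUE, n_perm = ncol(combos))
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_mc)) {
      idx_a <- sample.int(n, n_a)
      if (stat_for(idx_a) >= obs$chi2 - 1e-12) hits <- hits + 1L
    }
    list(p = (hits + 1) / (n_mc + 1), exact = FALSE, n_perm = n_mc)
  }
}
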