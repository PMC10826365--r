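#' Reference condition-level critical limits
#'
#' The condition-level summary (mean and 95% CI of dry-bulb temperature,
#' vapor pressure, and relative humidity at the critical limit, per group
#' and environmental condition) that the synthetic-data generator treats as
#' ground truth. Three groups (young-MinAct, older-MinAct, older-Rest) by
#' six conditions (P_crit at 34/36/38/40 degC; T_crit at 12/16 mmHg).
#'
#' @return Data.frame with one row per group-condition cell.
#' @export
reference_critical_loci <- function() {
  path <- system.file("extdata", "reference_critical_loci.csv",
                      package = "heatlimits", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference per-condition metabolic summary
#'
#' Condition-level means (and SDs where applicable) of net metabolic heat
#' production, oxygen consumption, METs, sweat rate, and percent body mass
#' loss for the three study groups; used as consistency anchors for the
#' calorimetry module and to parameterize the synthetic cohort's metabolic
#' draws.
#'
#' @return Data.frame with one row per group-condition cell.
#' @export
reference_metabolic <- function() {
  path <- system.file("extdata", "reference_metabolic.csv",
                      package = "heatlimits", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# SD implied by a t-based 95% CI half-width at sample size n
.sd_from_ci <- function(halfwidth, n = 8) {
  halfwidth * sqrt(n) / stats::qt(0.975, n - 1)
}

#' Synthetic trace specification
#'
#' Phenomenological model of one ramp trial: core temperature rises during
#' equilibration as a saturating exponential toward a plateau, drifts at
#' `slope_below` through the compensable stages, and from the moment the
#' ramped variable first exceeds `true_critical` rises at `slope_above`
#' (continuous hinge transition, or a 5-min logistic blend with
#' `transition = "smooth"`). AR(1) noise with stationary SD `noise_sd` is
#' superposed; the trace is fully determined by `seed`.
#'
#' @param schedule An [ramp_schedule()].
#' @param true_critical Ramped-variable value at which compensability is
#'   lost; `Inf` generates a censored (never-inflecting) trial.
#' @param t_gi_baseline Core temperature at trial start, degC.
#' @param equil_rise Amplitude of the equilibration rise, degC.
#' @param equil_tau Time constant of the equilibration rise, min.
#' @param slope_below,slope_above Core-temperature slopes below/above the
#'   critical limit, degC per h.
#' @param noise_sd Stationary SD of the AR(1) noise, degC.
#' @param ar1 AR(1) coefficient in \[0, 0.95\].
#' @param sample_interval Sampling interval, min.
#' @param duration Trace length, min; the default emulates the protocol's
#'   stopping rule (continue until the rise above the plateau is clearly
#'   sustained, ~0.5 degC, capped at 150 min total; 125 min when censored).
#' @param transition `"hinge"` (default) or `"smooth"` (logistic blend over
#'   5 min, to probe robustness to model mismatch).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return Object of class `hl_trace_spec`.
#' @export
trace_spec <- function(schedule, true_critical, t_gi_baseline = 37.0,
                       equil_rise = 0.4, equil_tau = 15,
                       slope_below = 0.10, slope_above = 0.62,
                       noise_sd = 0.05, ar1 = 0.8, sample_interval = 1,
                       duration = NULL, transition = c("hinge", "smooth"),
                       seed = NULL) {
  stopifnot(inherits(schedule, "hl_schedule"))
  transition <- match.arg(transition)
  if (slope_above <= slope_below) {
    stop("slope_above must exceed slope_below", call. = FALSE)
  }
  if (ar1 < 0 || ar1 > 0.95) stop("ar1 must lie in [0, 0.95]", call. = FALSE)
  if (is.finite(true_critical)) {
    k <- floor((true_critical - schedule$start_value) / schedule$step)
    t_inflect <- schedule$equilibration + schedule$step_interval * k
    if (k < 1 || t_inflect > 150) {
      stop("true_critical ", true_critical, " not reachable in (0, 150] min ",
           "from start value ", schedule$start_value, call. = FALSE)
    }
  } else {
    t_inflect <- Inf
  }
  if (is.null(duration)) {
    # protocol stopping rule: the trial continues until the rise above the
    # equilibrium plateau is clear and sustained (~0.5 degC), so shallow
    # above-limit slopes run longer; overall cap 150 min, floor 25 min past
    # the inflection. Censored trials stop after ~125 min.
    duration <- if (is.finite(t_inflect)) {
      post <- min(max(0.5 / slope_above * 60, 25), 90)
      min(t_inflect + post, 150)
    } else 125
  }
  structure(list(schedule = schedule, true_critical = true_critical,
                 t_inflect = t_inflect, t_gi_baseline = t_gi_baseline,
                 equil_rise = equil_rise, equil_tau = equil_tau,
                 slope_below = slope_below, slope_above = slope_above,
                 noise_sd = noise_sd, ar1 = ar1,
                 sample_interval = sample_interval, duration = duration,
                 transition = transition, seed = seed),
            class = "hl_trace_spec")
}

#' Generate a synthetic ramp-trial trace
#'
#' @param spec An [trace_spec()].
#' @return An [hl_trace()] object whose environmental series equals the
#'   schedule's commanded step function exactly.
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "hl_trace_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  sch <- spec$schedule
  t <- seq(0, spec$duration, by = spec$sample_interval)
  env <- env_at(sch, t)

  drift <- spec$slope_below / 60 * pmax(0, t - sch$equilibration)
  excess <- (spec$slope_above - spec$slope_below) / 60
  post <- if (is.finite(spec$t_inflect)) {
    if (spec$transition == "hinge") {
      excess * pmax(0, t - spec$t_inflect)
    } else {
      # logistic blend of the slope change over ~5 min around the inflection
      dt <- t - spec$t_inflect
      excess * 1.25 * log1p(exp(dt / 1.25))
    }
  } else {
    0
  }
  mu <- spec$t_gi_baseline +
    spec$equil_rise * (1 - exp(-t / spec$equil_tau)) + drift + post

  n <- length(t)
  z <- stats::rnorm(n)
  e <- numeric(n)
  e[1] <- spec$noise_sd * z[1]
  innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1^2)
  for (i in seq_len(n)[-1]) e[i] <- spec$ar1 * e[i - 1] + innov_sd * z[i]

  hl_trace(t, mu + e, env, fixed_value = sch$fixed_value, mode = sch$mode)
}

# draw (slope_below, slope_above) pairs with a detectability gap enforced by
# rejection; returns a 2-column matrix
.draw_slopes <- function(n, mean_below, sd_below, mean_above, sd_above,
                         min_gap = 0.2) {
  out <- matrix(NA_real_, n, 2)
  filled <- 0L
  while (filled < n) {
    m <- 2L * (n - filled)
    lo <- stats::rnorm(m, mean_below, sd_below)
    hi <- stats::rnorm(m, mean_above, sd_above)
    ok <- which(hi - lo >= min_gap)
    take <- utils::head(ok, n - filled)
    if (length(take)) {
      out[filled + seq_along(take), ] <- cbind(lo[take], hi[take])
      filled <- filled + length(take)
    }
  }
  out
}

#' Synthetic cohort specification
#'
#' Defines a study-shaped cohort: per condition-group cell a number of
#' trials, a true mean and SD for the critical value (defaults derived from
#' [reference_critical_loci()], with SDs back-calculated from the printed
#' 95% CIs assuming t-intervals at n = 8 per cell), anthropometric
#' distributions per age group, core-temperature slope distributions, and a
#' censoring rule for the 34 degC P_crit cells (a fixed number of subjects
#' whose core temperature never inflects).
#'
#' @param cells Data.frame with columns `group`, `age_group`, `activity`,
#'   `mode`, `condition`, `truth_mean`, `truth_sd`, `n`; default built from
#'   [reference_critical_loci()].
#' @param n_per_cell Trials per cell for the default table (default 8).
#' @param censor_34 Named integer vector: number of never-inflecting trials
#'   in the 34 degC P_crit cells by activity, default
#'   `c(Rest = 3, MinAct = 2)` (applied to older adults only).
#' @param noise_sd,ar1 Trace noise parameters (see [trace_spec()]).
#' @param seed RNG seed for the whole cohort.
#' @return Object of class `hl_cohort_spec`.
#' @export
cohort_spec <- function(cells = NULL, n_per_cell = 8,
                        censor_34 = c(Rest = 3, MinAct = 2),
                        noise_sd = 0.05, ar1 = 0.8, seed = 1) {
  if (is.null(cells)) {
    ref <- reference_critical_loci()
    ramped_mean <- ifelse(ref$mode == "P_crit", ref$p_a, ref$t_db)
    ramped_hw <- ifelse(ref$mode == "P_crit",
                        (ref$p_a_hi - ref$p_a_lo) / 2,
                        (ref$t_db_hi - ref$t_db_lo) / 2)
    cells <- data.frame(group = ref$group, age_group = ref$age_group,
                        activity = ref$activity, mode = ref$mode,
                        condition = ref$condition,
                        truth_mean = ramped_mean,
                        truth_sd = .sd_from_ci(ramped_hw, n_per_cell),
                        n = n_per_cell, stringsAsFactors = FALSE)
  }
  needed <- c("group", "age_group", "activity", "mode", "condition",
              "truth_mean", "truth_sd", "n")
  if (!all(needed %in% names(cells))) {
    stop("cells lacks columns: ",
         paste(setdiff(needed, names(cells)), collapse = ", "), call. = FALSE)
  }
  if (any(cells$truth_sd <= 0) || any(cells$n < 0)) {
    stop("truth_sd must be positive and n non-negative", call. = FALSE)
  }
  structure(list(cells = cells, censor_34 = censor_34, noise_sd = noise_sd,
                 ar1 = ar1, seed = seed),
            class = "hl_cohort_spec")
}

# anthropometric and metabolic sampling distributions per age group/activity
.anthro_defaults <- list(
  older = list(height = c(1.68, 0.10), bmi = c(26, 5), age = c(71, 6)),
  young = list(height = c(1.72, 0.10), bmi = c(25, 4), age = c(23, 4))
)
.vo2_defaults <- list(MinAct = c(0.45, 0.10), Rest = c(0.28, 0.06))
.slope_defaults <- list(
  `older-MinAct` = c(0.10, 0.12, 0.62, 0.48),
  `young-MinAct` = c(0.08, 0.13, 0.70, 0.54),
  `older-Rest` = c(0.07, 0.14, 0.69, 0.50)
)

#' Generate a synthetic study cohort
#'
#' Draws per-trial true critical values from the cell truth distributions,
#' subject anthropometrics from the age-group distributions, and slopes from
#' group-level distributions (rejection-sampled to keep the above-below gap
#' detectable); builds a full [trial_record()] per trial, plus a truth table
#' for parameter-recovery tests. Ramp start values sit 10 steps below the
#' rounded cell truth mean so inflections land well inside the trace; drawn
#' criticals are clamped to at least 3 steps above the start (the clamped
#' value is what the truth table records).
#'
#' @param spec An [cohort_spec()].
#' @return List with `records` (list of [trial_record()]) and `truth`
#'   (data.frame: trial_id, subject_id, group, age_group, activity, mode,
#'   condition, true_critical — `NA` for never-inflecting trials —,
#'   slope_below, slope_above, censored).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "hl_cohort_spec"))
  set.seed(spec$seed)
  records <- list()
  truth_rows <- list()
  trial_no <- 0L
  for (ci in seq_len(nrow(spec$cells))) {
    cell <- spec$cells[ci, ]
    if (cell$n == 0) next
    n_cens <- 0L
    if (cell$mode == "P_crit" && cell$condition == 34 &&
        cell$age_group == "older" && cell$activity %in% names(spec$censor_34)) {
      n_cens <- min(spec$censor_34[[cell$activity]], cell$n)
    }
    start <- round(cell$truth_mean) - 10
    sch <- ramp_schedule(mode = cell$mode, fixed_value = cell$condition,
                         start_value = start)
    sl_par <- .slope_defaults[[cell$group]]
    if (is.null(sl_par)) sl_par <- c(0.10, 0.12, 0.62, 0.48)
    slopes <- .draw_slopes(cell$n, sl_par[1], sl_par[2], sl_par[3], sl_par[4])
    crits <- stats::rnorm(cell$n, cell$truth_mean, cell$truth_sd)
    crits <- pmax(crits, start + 3)
    an <- .anthro_defaults[[cell$age_group]]
    vo2_par <- .vo2_defaults[[cell$activity]]
    for (j in seq_len(cell$n)) {
      trial_no <- trial_no + 1L
      censored <- j <= n_cens
      height <- min(max(stats::rnorm(1, an$height[1], an$height[2]), 1.45), 2.1)
      bmi <- min(max(stats::rnorm(1, an$bmi[1], an$bmi[2]), 17), 45)
      mass <- min(max(bmi * height^2, 40), 180)
      subj <- subject(id = sprintf("S%03d", trial_no),
                      age_group = cell$age_group, height_m = height,
                      mass_kg = mass,
                      age = round(stats::rnorm(1, an$age[1], an$age[2])))
      vo2 <- pmax(stats::rnorm(2, vo2_par[1], vo2_par[2]), 0.12)
      tsp <- trace_spec(sch,
                        true_critical = if (censored) Inf else crits[j],
                        slope_below = slopes[j, 1],
                        slope_above = slopes[j, 2],
                        noise_sd = spec$noise_sd, ar1 = spec$ar1,
                        seed = NULL)
      tr <- generate_trace(tsp)
      dur_h <- max(tr$t) / 60
      loss <- max(stats::rnorm(1, 0.0035, 0.0015), 0) * mass  # ~0.35% BML
      records[[trial_no]] <- trial_record(
        id = sprintf("T%03d", trial_no), subject = subj,
        activity = cell$activity, schedule = sch, tr = tr,
        vo2 = vo2, rer = 0.85,
        mass_pre = mass, mass_post = mass - loss)
      truth_rows[[trial_no]] <- data.frame(
        trial_id = sprintf("T%03d", trial_no),
        subject_id = subj$id, group = cell$group,
        age_group = cell$age_group, activity = cell$activity,
        mode = cell$mode, condition = cell$condition,
        true_critical = if (censored) NA_real_ else crits[j],
        slope_below = slopes[j, 1], slope_above = slopes[j, 2],
        censored = censored, stringsAsFactors = FALSE)
    }
  }
  list(records = records, truth = do.call(rbind, truth_rows))
}
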