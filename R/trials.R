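#' Ramp schedule
#'
#' The chamber protocol: after an equilibration period the ramped variable
#' (vapor pressure in P_crit trials, dry-bulb temperature in T_crit trials)
#' is raised by one step at the start of every interval. The commanded value
#' is modeled as a left-continuous step function: the first step takes
#' effect just after `equilibration` min, so `env_at(equilibration) ==
#' start_value` and `env_at(equilibration + k*interval)` has k steps applied.
#'
#' @param mode `"P_crit"` or `"T_crit"` (which variable is ramped).
#' @param fixed_value Held-constant variable: dry-bulb degC for P_crit
#'   (34/36/38/40 in the study-replication configs), vapor pressure mmHg for
#'   T_crit (12/16).
#' @param start_value Ramped variable's value during equilibration.
#' @param step Step size (+1 degC or +1 mmHg).
#' @param step_interval Minutes per step (default 5).
#' @param equilibration Equilibration duration, min (default 30).
#' @return Object of class `hl_schedule`.
#' @export
ramp_schedule <- function(mode = c("P_crit", "T_crit"), fixed_value,
                          start_value, step = 1, step_interval = 5,
                          equilibration = 30) {
  mode <- match.arg(mode)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (step_interval <= 0 || equilibration < 0) {
    stop("step_interval must be > 0 and equilibration >= 0", call. = FALSE)
  }
  structure(list(mode = mode, fixed_value = fixed_value,
                 start_value = start_value, step = step,
                 step_interval = step_interval, equilibration = equilibration),
            class = "hl_schedule")
}

#' Commanded environmental value at a given time
#'
#' @param schedule An [ramp_schedule()].
#' @param t Time since trial start, min. Vectorized.
#' @return Commanded ramped-variable value at each `t`.
#' @export
env_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "hl_schedule"))
  k <- ceiling(pmax(0, t - schedule$equilibration) / schedule$step_interval)
  schedule$start_value + k * schedule$step
}

#' Last fully completed ramp stage at a given time
#'
#' Stage k (value `start + k*step`) occupies the interval
#' `(equilibration + (k-1)*interval, equilibration + k*interval]`; it counts
#' as completed once its full interval has elapsed. Used as the censoring
#' lower bound for trials that end without an inflection.
#'
#' @inheritParams env_at
#' @param t_end End of the observed trace, min.
#' @return Ramped-variable value of the last completed stage (the start value
#'   if no stage completed).
#' @export
last_completed_stage <- function(schedule, t_end) {
  stopifnot(inherits(schedule, "hl_schedule"))
  k <- floor(max(0, t_end - schedule$equilibration) / schedule$step_interval)
  schedule$start_value + k * schedule$step
}

#' Heat-balance parameters for censored-limit estimation
#'
#' Conventional biophysical coefficients for still indoor air; these are not
#' study-specific measurements, and their influence on estimated limits is
#' bounded by the 5-mmHg clamp in [estimate_censored_limit()].
#'
#' @param t_sk Assumed mean skin temperature, degC (default 36).
#' @param h_c Convective heat transfer coefficient, W m^-2 K^-1 (default 4.3,
#'   still air).
#' @param h_r Radiative coefficient, W m^-2 K^-1 (default 4.7).
#' @param h_e Evaporative coefficient, W m^-2 mmHg^-1; default via the Lewis
#'   relation, 2.2 * h_c.
#' @param w_max Maximal skin wettedness in (0, 1]; default 0.65 (a
#'   conventional value for older adults; ~0.85 for young).
#' @return Object of class `hl_hbparams`.
#' @export
heat_balance_params <- function(t_sk = 36, h_c = 4.3, h_r = 4.7,
                                h_e = 2.2 * h_c, w_max = 0.65) {
  if (any(c(t_sk, h_c, h_r, h_e, w_max) <= 0) || w_max > 1) {
    stop("all parameters must be positive and w_max <= 1", call. = FALSE)
  }
  structure(list(t_sk = t_sk, h_c = h_c, h_r = h_r, h_e = h_e, w_max = w_max),
            class = "hl_hbparams")
}

#' Estimate the critical vapor pressure for a censored trial
#'
#' For 34 degC P_crit trials that end with no observed inflection, the
#' critical vapor pressure is estimated from the heat-balance boundary
#' E_req = E_max (required evaporation equals the evaporative maximum for the
#' wetted skin fraction):
#' P_est = P_sat(T_sk) - (M_net - (h_c + h_r) (T_sk - T_db)) / (w_max * h_e).
#' The estimate is clamped to `[last_stage, last_stage + 5]` mmHg: estimated
#' inflection points sit less than 5 mmHg above the final completed stage, so
#' the clamp bounds the influence of the conventional coefficients. When the
#' required evaporation is negative (dry heat loss alone balances M_net) the
#' upper clamp bound is returned with a warning.
#'
#' @param m_net Net metabolic heat production, W m^-2.
#' @param t_db Held dry-bulb temperature, degC.
#' @param last_stage Ramped-variable value of the last completed stage, mmHg.
#' @param hb An [heat_balance_params()] object.
#' @param clamp Width of the clamp above `last_stage`, mmHg (default 5).
#' @return Estimated critical vapor pressure, mmHg.
#' @export
estimate_censored_limit <- function(m_net, t_db, last_stage,
                                    hb = heat_balance_params(), clamp = 5) {
  stopifnot(inherits(hb, "hl_hbparams"))
  e_req <- m_net - (hb$h_c + hb$h_r) * (hb$t_sk - t_db)
  if (e_req < 0) {
    warning("required evaporation is negative (heat balance maintained by ",
            "dry exchange alone); returning the clamp upper bound")
    return(last_stage + clamp)
  }
  p_est <- saturation_vapor_pressure(hb$t_sk) - e_req / (hb$w_max * hb$h_e)
  min(max(p_est, last_stage), last_stage + clamp)
}

#' Trial record
#'
#' Bundles everything known about one experimental trial before analysis.
#'
#' @param id Trial label.
#' @param subject An [subject()] object.
#' @param activity `"MinAct"` or `"Rest"`.
#' @param schedule An [ramp_schedule()].
#' @param tr An [hl_trace()] object (its mode must match the schedule's).
#' @param vo2 Oxygen consumption sample(s), L per min (optional).
#' @param rer Respiratory exchange ratio sample(s) (optional).
#' @param mass_pre,mass_post Nude body mass before/after, kg (optional).
#' @return Object of class `hl_trial_record`.
#' @export
trial_record <- function(id, subject, activity = c("MinAct", "Rest"),
                         schedule, tr, vo2 = NULL, rer = NULL,
                         mass_pre = NULL, mass_post = NULL) {
  activity <- match.arg(activity)
  stopifnot(inherits(subject, "hl_subject"), inherits(schedule, "hl_schedule"),
            inherits(tr, "hl_trace"))
  if (attr(tr, "mode") != schedule$mode) {
    stop("trace mode ", attr(tr, "mode"), " does not match schedule mode ",
         schedule$mode, call. = FALSE)
  }
  structure(list(id = as.character(id), subject = subject,
                 activity = activity, schedule = schedule, trace = tr,
                 vo2 = vo2, rer = rer,
                 mass_pre = mass_pre, mass_post = mass_post),
            class = "hl_trial_record")
}

#' Analyze one ramp trial
#'
#' Full per-trial pipeline: inflection detection, critical environmental
#' value, below/above core-temperature slopes, and calorimetry derivations.
#' A trial with no detected inflection is censored at the last completed
#' ramp stage; censored 34 degC P_crit trials are additionally routed
#' through the heat-balance estimator (the only condition for which that
#' estimate is produced).
#'
#' @param record An [trial_record()].
#' @param search_start,min_slope_gap,alpha Passed to [detect_inflection()];
#'   `search_start = NULL` uses the schedule's equilibration + 15 min.
#' @param hb [heat_balance_params()] for censored-limit estimation. Skin
#'   wettedness defaults by age group (0.65 older, 0.85 young) when `hb` is
#'   `NULL`.
#' @param slope_window,slope_guard Window and guard gap for
#'   [tgi_rate_of_change()], min.
#' @return Object of class `hl_trial_result`: a one-row data.frame with
#'   columns trial_id, subject_id, age_group, activity, mode, condition
#'   (fixed value), critical_value, t_db, p_a, rh, censored, estimation,
#'   breakpoint_time, slope_below, slope_above, m_net, mets, sr, bml.
#' @export
analyze_trial <- function(record, search_start = NULL, min_slope_gap = 0.1,
                          alpha = 0.05, hb = NULL, slope_window = 20,
                          slope_guard = 5) {
  stopifnot(inherits(record, "hl_trial_record"))
  sch <- record$schedule
  tr <- record$trace
  if (is.null(search_start)) search_start <- sch$equilibration + 15
  if (is.null(hb)) {
    w <- if (record$subject$age_group == "young") 0.85 else 0.65
    hb <- heat_balance_params(w_max = w)
  }

  # trial exclusion rules
  if (max(tr$t) < 45) {
    stop("trial ", record$id, ": trace shorter than 45 min; excluded",
         call. = FALSE)
  }

  # calorimetry (optional inputs)
  a_d <- record$subject$a_d
  m_net <- mets <- sr <- bml <- NA_real_
  if (!is.null(record$vo2)) {
    rer <- if (is.null(record$rer)) 0.85 else record$rer
    if (length(record$vo2) == 1) {
      message("trial ", record$id, ": single metabolic sample; using alone")
    }
    m_net <- metabolic_heat_production(record$vo2, rer, a_d)
    mets <- mean(mets_from_vo2(record$vo2, record$subject$mass_kg))
  }
  if (!is.null(record$mass_pre) && !is.null(record$mass_post)) {
    swr <- sweat_rate(record$mass_pre, record$mass_post,
                      duration_h = max(tr$t) / 60, a_d = a_d)
    sr <- swr$sr
    bml <- swr$bml
  }

  fit <- detect_inflection(tr, search_start = search_start,
                           min_slope_gap = min_slope_gap, alpha = alpha)
  slope_below <- slope_above <- bp <- NA_real_
  if (fit$detected) {
    critical <- critical_env_value(tr, fit)
    sl <- tgi_rate_of_change(tr, fit, window = slope_window,
                             guard = slope_guard)
    slope_below <- sl$below
    slope_above <- sl$above
    bp <- fit$breakpoint_time
    censored <- FALSE
    estimation <- "observed"
  } else {
    last <- last_completed_stage(sch, max(tr$t))
    if (sch$mode == "P_crit" && isTRUE(all.equal(sch$fixed_value, 34)) &&
        is.finite(m_net)) {
      critical <- estimate_censored_limit(m_net, t_db = sch$fixed_value,
                                          last_stage = last, hb = hb)
      censored <- FALSE
      estimation <- "heat_balance_estimated"
    } else {
      critical <- last
      censored <- TRUE
      estimation <- "observed"
    }
  }

  # locus: P_crit -> (fixed T_db, critical P_a); T_crit -> (critical T_db,
  # fixed P_a). Axis roles never swap.
  if (sch$mode == "P_crit") {
    t_db <- sch$fixed_value
    p_a <- critical
  } else {
    t_db <- critical
    p_a <- sch$fixed_value
  }
  rh <- relative_humidity(t_db, p_a, allow_supersaturation = TRUE)

  out <- data.frame(
    trial_id = record$id, subject_id = record$subject$id,
    age_group = record$subject$age_group, activity = record$activity,
    mode = sch$mode, condition = sch$fixed_value,
    critical_value = critical, t_db = t_db, p_a = p_a, rh = rh,
    censored = censored, estimation = estimation,
    breakpoint_time = bp, slope_below = slope_below,
    slope_above = slope_above,
    m_net = m_net, mets = mets, sr = sr, bml = bml,
    stringsAsFactors = FALSE
  )
  class(out) <- c("hl_trial_result", "data.frame")
  out
}

#' Analyze a batch of trials
#'
#' Order-preserving wrapper around [analyze_trial()]; failures are logged per
#' trial and the remaining trials still run.
#'
#' @param records List of [trial_record()] objects.
#' @param ... Passed to [analyze_trial()].
#' @return A data.frame of row-bound trial results.
#' @export
analyze_trials <- function(records, ...) {
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rows[[i]] <- tryCatch(analyze_trial(records[[i]], ...), error = function(e) {
      warning("trial ", records[[i]]$id, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hl_trial_result", "data.frame")
  out
}
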