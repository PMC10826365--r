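#' Saturation vapor pressure of water
#'
#' Closed-form correlation for the saturation water vapor pressure over liquid
#' water at a given dry-bulb temperature. The default is the Antoine equation
#' with the 1-100 degC constants for water, which is accurate to well under
#' 0.1% across the 33-50 degC range spanned by chamber heat-stress trials.
#' The Arden Buck correlation is available as an alternative strategy.
#'
#' @param t_db Dry-bulb temperature, degC. Vectorized.
#' @param method Correlation to use: `"antoine"` (default) or `"buck"`.
#' @return Saturation vapor pressure, mmHg.
#' @examples
#' saturation_vapor_pressure(36.2)
#' saturation_vapor_pressure(100) # ~760 mmHg at 1 atm
#' @export
saturation_vapor_pressure <- function(t_db, method = c("antoine", "buck")) {
  method <- match.arg(method)
  if (!is.numeric(t_db) || anyNA(t_db)) {
    stop("t_db must be numeric with no missing values", call. = FALSE)
  }
  if (any(t_db < -10 | t_db > 100)) {
    stop("t_db outside correlation validity range [-10, 100] degC",
         call. = FALSE)
  }
  switch(method,
    antoine = 10^(8.07131 - 1730.63 / (233.426 + t_db)),
    buck = {
      hpa <- 6.1121 * exp((18.678 - t_db / 234.5) * t_db / (257.14 + t_db))
      hpa * 0.7500617
    }
  )
}

#' Relative humidity from vapor pressure
#'
#' rh = 100 * P_a / P_sat(T_db). rh is always derived, never stored, so a
#' (T_db, P_a) pair can never carry an inconsistent humidity.
#'
#' @param t_db Dry-bulb temperature, degC.
#' @param p_a Ambient water vapor pressure, mmHg.
#' @param allow_supersaturation If `FALSE` (default), P_a above saturation is
#'   an error; if `TRUE`, rh > 100 is returned as-is.
#' @inheritParams saturation_vapor_pressure
#' @return Relative humidity, percent.
#' @export
relative_humidity <- function(t_db, p_a, allow_supersaturation = FALSE,
                              method = c("antoine", "buck")) {
  if (any(p_a < 0)) stop("p_a must be non-negative", call. = FALSE)
  psat <- saturation_vapor_pressure(t_db, method = match.arg(method))
  rh <- 100 * p_a / psat
  if (!allow_supersaturation && any(rh > 100 + 1e-9)) {
    stop("p_a exceeds saturation; set allow_supersaturation = TRUE to permit",
         call. = FALSE)
  }
  rh
}

#' Vapor pressure from relative humidity
#'
#' Inverse of [relative_humidity()]: P_a = rh/100 * P_sat(T_db).
#'
#' @inheritParams relative_humidity
#' @param rh Relative humidity, percent, in \[0, 100\].
#' @return Ambient water vapor pressure, mmHg.
#' @export
vapor_pressure_from_rh <- function(t_db, rh, method = c("antoine", "buck")) {
  if (any(rh < 0 | rh > 100)) {
    stop("rh must lie in [0, 100]", call. = FALSE)
  }
  rh / 100 * saturation_vapor_pressure(t_db, method = match.arg(method))
}

#' Psychrometric state
#'
#' Bundles a dry-bulb temperature and vapor pressure; relative humidity is
#' derived on construction and never stored independently.
#'
#' @inheritParams relative_humidity
#' @return A data.frame with columns `t_db` (degC), `p_a` (mmHg), `rh` (%).
#' @export
psychro_state <- function(t_db, p_a, allow_supersaturation = FALSE) {
  rh <- relative_humidity(t_db, p_a,
                          allow_supersaturation = allow_supersaturation)
  data.frame(t_db = t_db, p_a = p_a, rh = rh)
}

#' @rdname unit_conversions
#' @name unit_conversions
#' @title Pressure unit conversions at the package boundary
#' @description All internal computation is in mmHg (the convention of
#'   psychrometric-limit work); these helpers convert at the boundary only.
#' @param x Pressure value(s).
#' @return Converted pressure value(s).
#' @export
mmhg_to_kpa <- function(x) x * 0.1333224

#' @rdname unit_conversions
#' @export
kpa_to_mmhg <- function(x) x / 0.1333224
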