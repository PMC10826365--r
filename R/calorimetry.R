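#' DuBois body surface area
#'
#' A_D = 0.007184 * mass^0.425 * height_cm^0.725, the DuBois-DuBois power law.
#'
#' @param height_m Height, m.
#' @param mass_kg Body mass, kg.
#' @return Body surface area, m^2.
#' @examples
#' dubois_bsa(1.68, 73.4)
#' @export
dubois_bsa <- function(height_m, mass_kg) {
  if (any(height_m <= 0) || any(mass_kg <= 0)) {
    stop("height and mass must be positive", call. = FALSE)
  }
  0.007184 * mass_kg^0.425 * (height_m * 100)^0.725
}

# kJ per litre O2 for pure carbohydrate / pure fat oxidation
.kj_per_l_carb <- 21.13
.kj_per_l_fat <- 19.62

#' Energy equivalent of oxygen
#'
#' kJ released per litre O2 consumed, linearly interpolated between the fat
#' (RER 0.70) and carbohydrate (RER 1.00) equivalents; RER outside that range
#' is clamped (protein oxidation and non-metabolic CO2 are ignored, standard
#' in partitional calorimetry).
#'
#' @param rer Respiratory exchange ratio (dimensionless).
#' @param kj_carb,kj_fat Energy equivalents at RER 1.00 / 0.70, kJ per litre
#'   O2. Defaults 21.13 and 19.62.
#' @return kJ per litre O2.
#' @export
energy_equivalent <- function(rer, kj_carb = .kj_per_l_carb,
                              kj_fat = .kj_per_l_fat) {
  f <- pmin(pmax((rer - 0.7) / 0.3, 0), 1)
  kj_carb * f + kj_fat * (1 - f)
}

#' Net metabolic heat production
#'
#' Partitional-calorimetry net heat production per unit body surface area:
#' M_net = (VO2 * e(RER) * 1000/60 - external_work) / A_D, in W per m^2,
#' where e(RER) is the energy equivalent of oxygen. With measurements taken
#' at two time points (typically 5 and 60 min into a trial) the per-trial
#' value is their mean; pass vectors to average.
#'
#' @param vo2 Oxygen consumption, L per min. May be length > 1 (samples are
#'   averaged after conversion to heat production).
#' @param rer Respiratory exchange ratio, in \[0.67, 1.3\]; recycled to
#'   length of `vo2`.
#' @param a_d Body surface area, m^2.
#' @param external_work External work rate, W (0 for seated rest and
#'   zero-resistance pedaling).
#' @inheritParams energy_equivalent
#' @return Net metabolic heat production, W per m^2 (scalar).
#' @examples
#' metabolic_heat_production(0.43, 0.85, 1.82)
#' @export
metabolic_heat_production <- function(vo2, rer, a_d, external_work = 0,
                                      kj_carb = .kj_per_l_carb,
                                      kj_fat = .kj_per_l_fat) {
  if (a_d <= 0) stop("a_d must be positive", call. = FALSE)
  if (any(vo2 <= 0)) stop("vo2 must be positive", call. = FALSE)
  if (any(rer < 0.67 | rer > 1.3)) {
    stop("rer outside physiological range [0.67, 1.3]", call. = FALSE)
  }
  if (external_work < 0) stop("external_work must be >= 0", call. = FALSE)
  rer <- rep_len(rer, length(vo2))
  watts <- vo2 * energy_equivalent(rer, kj_carb, kj_fat) * 1000 / 60
  mean((watts - external_work) / a_d)
}

#' Metabolic equivalents from oxygen consumption
#'
#' METs = (VO2 in mL/kg/min) / 3.5, using the conventional resting oxygen
#' uptake of 3.5 mL per kg per min.
#'
#' @inheritParams metabolic_heat_production
#' @param mass_kg Body mass, kg.
#' @param resting_vo2 Assumed resting uptake, mL per kg per min.
#' @return METs (dimensionless).
#' @export
mets_from_vo2 <- function(vo2, mass_kg, resting_vo2 = 3.5) {
  if (any(mass_kg <= 0)) stop("mass must be positive", call. = FALSE)
  (vo2 * 1000 / mass_kg) / resting_vo2
}

#' Whole-body sweat rate and percent body mass loss
#'
#' Computed from nude body mass before and after a trial. Masses are
#' quantized to the 10-g resolution of the laboratory scale before
#' differencing, so sub-10-g perturbations cannot change the output. Fluid
#' intake is assumed absent between weighings; a mass gain is a warning (not
#' an error) and yields a non-positive sweat rate.
#'
#' @param mass_pre,mass_post Nude body mass before/after, kg.
#' @param duration_h Trial duration, h, in (0.5, 4\].
#' @param a_d Body surface area, m^2.
#' @return List with `sr` (sweat rate, g per m^2 per h) and `bml`
#'   (percent body mass loss).
#' @examples
#' sweat_rate(73.40, 73.12, duration_h = 2, a_d = 1.82)
#' @export
sweat_rate <- function(mass_pre, mass_post, duration_h, a_d) {
  if (duration_h <= 0) stop("duration must be positive", call. = FALSE)
  if (duration_h <= 0.5 || duration_h > 4) {
    warning("duration ", duration_h, " h outside the typical (0.5, 4] h range")
  }
  if (mass_post > mass_pre) {
    warning("body mass increased over the trial; check the mass balance")
  }
  # 10 g = 0.01 kg scale resolution
  pre <- round(mass_pre * 100) / 100
  post <- round(mass_post * 100) / 100
  loss_kg <- pre - post
  list(
    sr = loss_kg * 1000 / (a_d * duration_h),
    bml = 100 * loss_kg / pre
  )
}

#' Subject record
#'
#' Anthropometrics for one subject; DuBois surface area and the area-to-mass
#' ratio are derived on construction.
#'
#' @param id Opaque subject label.
#' @param age_group `"young"` or `"older"`.
#' @param height_m Height, m, in \[1.2, 2.2\].
#' @param mass_kg Mass, kg, in \[35, 200\].
#' @param age Age, years (optional).
#' @param vo2max Maximal oxygen uptake, mL per kg per min (optional).
#' @return An object of class `hl_subject` (a list).
#' @export
subject <- function(id, age_group = c("older", "young"), height_m, mass_kg,
                    age = NA_real_, vo2max = NA_real_) {
  age_group <- match.arg(age_group)
  if (height_m < 1.2 || height_m > 2.2) {
    stop("height ", height_m, " m outside plausible range [1.2, 2.2]",
         call. = FALSE)
  }
  if (mass_kg < 35 || mass_kg > 200) {
    stop("mass ", mass_kg, " kg outside plausible range [35, 200]",
         call. = FALSE)
  }
  a_d <- dubois_bsa(height_m, mass_kg)
  structure(
    list(id = as.character(id), age_group = age_group, age = age,
         height_m = height_m, mass_kg = mass_kg, a_d = a_d,
         a_d_per_kg = a_d / mass_kg, vo2max = vo2max),
    class = "hl_subject"
  )
}

#' @export
print.hl_subject <- function(x, ...) {
  cat(sprintf("<subject %s> %s, %.2f m, %.1f kg, A_D %.2f m^2\n",
              x$id, x$age_group, x$height_m, x$mass_kg, x$a_d))
  invisible(x)
}
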