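# shared fixtures built in code

# flat plateau for `flat_min` minutes then a linear rise, on a P_crit ramp
flat_rise_trace <- function(flat_min = 60, total = 100, rise_per_h = 0.7,
                            noise_sd = 0, baseline = 37,
                            sch = ramp_schedule("P_crit", 40, 20), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- 0:total
  mu <- baseline + rise_per_h / 60 * pmax(0, t - flat_min)
  y <- mu + if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
  hl_trace(t, y, env_at(sch, t), attr_fixed(sch), sch$mode)
}

attr_fixed <- function(sch) sch$fixed_value

# small standard subject used across trial tests
test_subject <- function(id = "S1", age_group = "older") {
  subject(id, age_group = age_group, height_m = 1.68, mass_kg = 73.4)
}
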