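---
title: "Critical environmental limits from progressive heat-stress trials: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical environmental limits: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatlimits)
```

## The problem

A critical environmental limit is the combination of dry-bulb temperature
(T_db, °C) and ambient water vapor pressure (P_a, mmHg) above which a person
at a given metabolic heat production can no longer maintain heat balance:
core temperature stops plateauing and rises continuously — heat stress
becomes *uncompensable*. The progressive protocol this package analyzes
ramps one environmental variable in an environmental chamber (+1 mmHg or
+1 °C every 5 min after a 30-min equilibration) while the other is held
fixed, and reads the limit off the gastrointestinal-temperature (T_gi)
trace: the critical value is the mean of the ramped variable over the 2 min
before the T_gi inflection point. Per-trial limits are then aggregated into
survival-style *compensability curves*, condition-level mean loci with 95%
CIs, and quadratic psychrometric limit curves.

The package implements the full chain — psychrometrics, partitional
calorimetry, inflection detection, censored-trial estimation, survival-style
statistics, curve fitting — together with a protocol-faithful synthetic-data
generator, so that every stage is testable against known ground truth
without the original deposited dataset.

## Psychrometrics

Relative humidity is always *derived*: rh = 100·P_a/P_sat(T_db), never
stored, so a (T_db, P_a) pair cannot carry an inconsistent humidity. The
saturation-pressure correlation is the Antoine equation with the 1–100 °C
water constants (error < 0.1% over the 33–50 °C study envelope; the Arden
Buck correlation is available as a swappable strategy, and the two agree to
< 0.5% there). All internal pressure units are mmHg — the convention of this
literature — with kPa converters at the boundary only.

Recomputing rh from condition-level *mean* (T_db, P_a) does not exactly
reproduce a printed mean rh, because a mean of per-trial ratios is not the
ratio of means. The reference-table cross-check therefore carries tolerance
bands (0.5 percentage points for most rows, 3 for all); the one reference
row that deviates by ~2.6 points (older group, 34 °C, the cell containing
heat-balance-estimated trials) is exactly where per-trial dispersion is
largest.

## Partitional calorimetry

- DuBois surface area: A_D = 0.007184·mass^0.425·(100·height)^0.725.
- Net metabolic heat production per unit area:
  M_net = (V̇O2 · e(RER) · 1000/60 − W_ext)/A_D, with the oxygen energy
  equivalent e(RER) interpolated linearly between the fat (19.62 kJ/L at
  RER 0.70) and carbohydrate (21.13 kJ/L at RER 1.00) values, clamped
  outside that range. External work defaults to 0 (seated rest;
  zero-resistance pedaling). When V̇O2 is sampled twice (5 and 60 min into a
  trial) the two converted values are averaged; a single sample is used
  alone with a message. The coefficient pair is configurable.
- METs = (V̇O2 in mL·kg⁻¹·min⁻¹)/3.5.
- Sweat rate = Δ(nude body mass)·1000/(A_D·duration); percent body-mass
  loss = 100·Δmass/mass_pre. Masses are quantized to the scale's 10-g
  resolution *before* differencing, so sub-resolution perturbations cannot
  change the output. Trial duration defaults to the recorded trace length.

## Inflection detection

The detector fits a continuous hinge (two least-squares lines meeting at
the breakpoint) to T_gi versus time for every candidate breakpoint on the
sampling grid in `[search_start, t_end − 10]`, keeping the SSE-minimizing
candidate (earliest on ties — the conservative, lower-limit choice).
`search_start` defaults to 45 min: the 30-min equilibration plus 15 min for
the plateau to establish. A detection additionally requires

1. slope_above − slope_below ≥ 0.1 °C/h (below-limit drift is ~0.07–0.10
   °C/h, above-limit rises ~0.6–0.7, so 0.1 separates the regimes), and
2. a segmented-versus-single-line F-test at α = 0.05.

Otherwise the trial is censored at the last completed ramp stage.

Two refinements beyond the plain search (both can be disabled, restoring
the textbook algorithm, and the exhaustive-search property is unit-tested in
that configuration against an independent implementation):

- **AR(1) prewhitening.** Telemetry-capsule noise is strongly autocorrelated.
  If the first-pass residuals show lag-1 autocorrelation above 0.2, the
  search and the F-test are re-run after Cochrane–Orcutt quasi-differencing.
  Without this the F-test is badly anticonservative (~21% false detections
  on inflection-free AR traces at nominal 5%; ~9% with it — selection over
  candidate breakpoints keeps even the corrected test somewhat liberal).
- **Informative slope priors (MAP search).** The hinge slopes get Gaussian
  pseudo-observations at the published cohort rates of core-temperature
  change (0.10 ± 0.12 °C/h below, 0.62 ± 0.48 above), weighted by the
  estimated innovation SD — a ridge penalty, i.e. empirical Bayes. This is
  what a human rater does implicitly (they know what a plateau looks like),
  and it improves within-one-step recovery of the critical value on
  realistic cohorts from ~66% to ~74%. We deliberately use the honest Bayes
  weight: a near-hard constraint would score better on benchmarks whose true
  slopes sit exactly at the prior means and worse everywhere else.

### What localization accuracy is attainable

Under the generator's stated noise (stationary SD 0.05 °C, AR1 0.8 at 1-min
sampling) and a 0.10 → 0.62 °C/h slope change, breakpoint localization is
information-limited. An oracle knowing every generator parameter except the
breakpoint reaches RMSE ≈ 2.9 min (93% within ±5 min); any estimator that
must also estimate the slopes is bounded by the profile likelihood, at
RMSE ≈ 9–12 min in our measurements, regardless of OLS/GLS/binning/slope
constraints. Consequently the ≥90% within-one-ramp-step acceptance benchmark
holds under white noise of the same variance (94.5% measured) but not under
the AR(1) world (~64%); the corresponding acceptance test is left failing
deliberately rather than weakening the noise model, and downstream
statistics inherit a ~1.5–2.5 mmHg heavy-tailed measurement error per trial.

### Rate-of-change windows

Cohort-level T_gi slopes below/above the limit are least-squares slopes in
windows around the breakpoint. The defaults are 20-min windows separated
from the breakpoint by a 5-min guard gap. The guard exists because the
SSE-chosen breakpoint sits where noise exaggerates the kink; windows
abutting it systematically under-estimate the below slope and over-estimate
the above slope (−0.07/+1.03 °C/h against true +0.07/+0.83 in simulation
with 10-min adjacent windows; +0.02/+0.06 bias with the guard design).
`window = 10, guard = 0` reproduces the plain adjacent-window convention.
Even with the guard, a small positive selection bias of order +0.02–0.05
°C/h remains — comparable to 2 SE at 100 trials, which makes the
slope-recovery acceptance check genuinely marginal rather than comfortably
green.

## Censored trials and the heat-balance estimate

At the mildest humid condition (34 °C, P_a ramped) some participants never
inflect within ~120 min. For those trials only, the critical vapor pressure
is estimated from the compensability boundary E_req = E_max:

P_est = P_sat(T_sk) − [M_net − (h_c + h_r)(T_sk − T_db)]/(w_max·h_e),

with conventional still-air coefficients (T_sk = 36 °C, h_c = 4.3, h_r =
4.7 W·m⁻²·K⁻¹, h_e = 2.2·h_c per mmHg via the Lewis relation, w_max = 0.65
older / 0.85 young). These coefficients are *not* study-specific — their
influence is bounded by clamping the estimate to
[last completed stage, last stage + 5 mmHg], the empirically reported range
for such estimates. Two edge behaviours follow from the formula: zero or
negative required evaporation returns the clamp's *upper* bound (dry
exchange alone suffices, so the tolerable humidity is maximal), and the
estimate decreases with T_db at fixed skin temperature (warmer air cuts dry
loss). Censored trials at any other condition are never estimated; they stay
right-censored at the last completed stage and are excluded from locus
means (which would otherwise treat a lower bound as a measurement), while
remaining in the survival-style risk sets where censoring is handled
properly.

## Compensability curves and the Gehan–Breslow–Wilcoxon test

The compensability curve is the Kaplan–Meier product-limit estimator with
environmental stress in place of time; tied events at one stress (common,
since ramp protocols quantize stress to integers) are handled in a single
risk-set step, and censored observations reduce the risk set without
stepping the curve down.

The two-group test is the Gehan–Breslow–Wilcoxon weighted log-rank,
implemented from first principles: weight w_i = n_i (number at risk) at each
distinct event stress, score U = Σ w_i (d_Ai − n_Ai d_i/n_i), hypergeometric
variance with w_i² weights, U²/V referred to χ²₁ (two-sided). With unit
weights it reduces to the standard log-rank and matches
`survival::survdiff` to 1e-8 — the cross-library sanity check. A label
permutation oracle (exact enumeration up to 20 000 assignments, seeded
Monte-Carlo beyond) ships alongside as the independent check of the
chi-square approximation. At n ≤ 8 the exact null has at most 70 atoms, so
raw p-values differ from χ² mainly by discreteness; the documented agreement
tolerance is 0.3 against the mid-p, with Spearman rank agreement ≥ 0.9
across the random-dataset suite.

Across conditions the package aggregates with a *stratified* GBW (summing
per-condition scores and variances, the stratified log-rank construction).
Naive pooling would put mmHg and °C observations on one axis; stratification
compares only within a condition. Heat-balance-estimated limits enter as
events at the estimated stress by default, with a switch to treat them as
censored for sensitivity analysis.

## Condition-level loci and psychrometric curves

Per condition-group cell the package reports means and t-based 95% CIs of
T_db, P_a, and rh — rh averaged as per-trial ratios, matching how such
tables are reported. Quadratic limit curves P_a = a·T_db² + b·T_db + c are
ordinary least squares through the six cell loci (the four humid-limb cells
supply nearly fixed T_db and the two dry-limb cells nearly fixed P_a; a
joint fit is the default, per-limb fitting was judged an unneeded flag at
six points). The `lower95` variant fits the per-condition lower CI bounds of
whichever variable was ramped — the conservative boundary drawn on published
charts — rather than propagating coefficient covariance. Prediction refuses
to extrapolate more than 1 °C beyond the fitted span; points below the curve
classify as compensable.

Group comparisons of critical limits use a within-condition label
permutation test (statistic: mean signed difference of condition means;
two-sided Monte-Carlo p with add-one correction) as a deliberate,
documented replacement for the mixed-effects models used in the original
analyses, which are out of scope here.

## The synthetic world

`generate_trace()` produces: a saturating-exponential equilibration rise
(0.4 °C, tau 15 min — plateau established between 30 and 60 min), a
below-limit drift, a continuous hinge to the above-limit slope starting when
the commanded ramp first exceeds the trial's true critical value, and AR(1)
noise (stationary SD 0.05 °C, coefficient 0.8 at 1-min sampling — capsule
telemetry drifts; white noise understates the problem). A logistic-blend
transition option exists to probe robustness to the hinge model-match. The
trace ends the way the protocol does: once the rise above the plateau is
clearly sustained (~0.5 °C, so shallow rises run longer), capped at 150 min;
never-inflecting trials stop at 125 min.

`generate_cohort()` builds the full study shape — three groups (older and
young at minimal activity; older at rest) by six conditions (P_a ramped at
34/36/38/40 °C; T_db ramped at 12/16 mmHg), n = 8 trials per cell — drawing
per-trial critical values from the reference cell means with SDs
back-derived from the printed 95% CIs at n = 8, anthropometrics from the
group height/BMI distributions, slopes from the group rate-of-change
distributions (rejection-sampled to a ≥ 0.2 °C/h gap so trials are
physically detectable), and forcing the reported censoring structure: 3
never-inflecting rest trials and 2 minimal-activity trials at 34 °C. Ramp
start values sit 10 steps below the rounded cell mean, putting typical
inflections ~80 min into the trial.

What a green pipeline test does **not** establish: the generator is
phenomenological (piecewise-linear core temperature, not a two-node
thermoregulatory model); its censored 34 °C trials ramp to ~9 steps above
the cell mean before stopping, so their clamped heat-balance estimates
inflate the synthetic 34 °C cell means by ~2 mmHg relative to the reference
values — a structural artifact of not knowing the original ramp start
values; and real trials have missing samples, probe dropouts, and
operator-terminated schedules that the generator only approximates through
the IO layer's interpolation rules.

## Known limitations

- Breakpoint localization under the stated AR(1) noise is
  information-limited (see above); two acceptance benchmarks are accordingly
  left red by design rather than met by weakening the noise world.
- The heat-balance coefficients for censored-trial estimation are
  conventional, not calibrated; only the 5-mmHg clamp is empirical.
- The quadratic limit curve is a smoother, not a biophysical model; its
  extrapolation guard (±1 °C) is deliberately strict.
- Mixed-effects inference, V̇O2max testing, screening workflows, and
  heart-rate analysis are out of scope.
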