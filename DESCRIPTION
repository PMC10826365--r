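Package: heatlimits
Title: Critical Environmental Limits for Human Heat Stress Compensability
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for progressive heat-stress chamber trials in
    which ambient dry-bulb temperature or water vapor pressure is ramped in
    steps until core (gastrointestinal) temperature departs from its
    equilibrium plateau. Provides psychrometric primitives, partitional
    calorimetry (DuBois surface area, net metabolic heat production, METs,
    sweat rate), segmented-regression detection of the core-temperature
    inflection point and the critical environmental value it defines,
    Kaplan-Meier style compensability curves with the Gehan-Breslow-Wilcoxon
    test implemented from first principles, quadratic psychrometric limit
    curves with confidence bounds, a permutation test for group differences,
    and a protocol-faithful synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
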