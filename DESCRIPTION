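Package: ffmbia
Title: Fat-Free Mass Prediction Equations for Bioelectrical Impedance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A library of published bioelectrical-impedance-analysis (BIA)
    fat-free-mass (FFM) prediction equations for adolescents and adults,
    together with the validation machinery used to compare them against
    dual-energy X-ray absorptiometry (DXA): per-subject accuracy
    classification at a configurable cutoff, group-level bias, root mean
    squared prediction error, a lexicographic best-equation ranking rule,
    and paired change-agreement testing for longitudinal follow-up.
    Includes forward-selection linear-regression tools for developing new
    population-specific equations and a moment-calibrated synthetic cohort
    generator emulating an obese-adolescent study population, so that every
    stage of the pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
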