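Package: gwgmediate
Title: Causal Mediation of Maternal Pre-Pregnancy BMI Effects on Child
    Obesity via Gestational Weight Gain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counterfactual mediation analysis of the effect of maternal
    pre-pregnancy body mass index on child age-4 BMI z-score, mediated by
    excessive gestational weight gain (IOM categories). Provides the
    closed-form controlled/natural direct and indirect effect decomposition
    for a continuous outcome and binary mediator with exposure-mediator
    interaction, percentile-bootstrap inference, a Monte-Carlo
    potential-outcomes oracle, LMS growth-reference z-scores, monotonic
    cleaning of longitudinal child height records, fully-conditional-
    specification multiple imputation with Rubin pooling, and a synthetic
    mother-child cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
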