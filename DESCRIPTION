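Package: qreveal
Title: Revealing-Truth Probability for Validating Patient-Reported
    Outcome Measures Against a Continuous Objective Endpoint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the conditional probability Q that a dichotomized
    patient-reported outcome (PRO) reveals a subject's true disease status
    relative to a subject-specific latent threshold on a continuous
    objective endpoint. Provides the per-subject threshold-scan estimator
    of Q and of the latent threshold from repeated paired observations,
    exact binomial (Clopper-Pearson) confidence intervals, population-level
    inference across subjects including a minimum-acceptable-probability
    test and responsiveness analysis of threshold shifts across
    dichotomization cutoffs via a Wilcoxon signed-rank test, and a
    Monte-Carlo simulation framework with correlated multivariate-normal
    objective outcomes for studying the estimator's operating
    characteristics. Works with or without correlation among the repeated
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
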