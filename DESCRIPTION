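Package: ecwm
Title: Prevalence Estimation for Sensitive Behaviours with the Extended
    Crosswise Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design, simulation and analysis tools for surveys that measure
    sensitive behaviours with the crosswise model (CWM) and its two-group
    extension (ECWM) alongside conventional direct questioning (DQ).
    Provides the crosswise measurement model and its moment estimator,
    joint maximum-likelihood pooling of the two ECWM groups, a
    likelihood-ratio G2 test for instruction non-adherence, two-proportion
    comparison of DQ and ECWM prevalence estimates,
    measurement-model-adjusted ("randomized response") logistic regression
    of the latent sensitive status on covariates, variance-inflation and
    sample-size planning, a seeded respondent-level survey simulator, and
    a report pipeline from respondent CSV to tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
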