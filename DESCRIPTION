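Package: ipvconsist
Title: Consistency of Longitudinal Self-Reported Intimate Partner Violence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the consistency of repeated yes/no survey
    answers to a lifetime intimate partner violence (IPV) item across a
    six-wave women's health cohort. Classifies each woman's answered
    response sequence into six consistency classes, derives longitudinal
    covariates (relationship trajectory, sustained partner and income
    stress, design weights for rural oversampling), produces weighted
    descriptive tables, and fits a baseline-category multinomial logistic
    regression of consistency class on covariates with the consistently
    reporting group as reference. A synthetic-cohort generator with an
    explicit latent-onset, false-positive/false-negative misreporting and
    attrition model, together with an exact enumeration oracle for the
    consistency-class distribution, supports validation, calibration and
    cross-sectional bias analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nnet,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
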