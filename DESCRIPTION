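Package: ceatrial
Title: Trial-Based Cost-Effectiveness and Cost-Utility Analysis from a
    Societal Perspective
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for trial-based economic evaluation of telemonitoring
    interventions in inflammatory bowel disease from a societal perspective:
    per-patient cost accounting (health care, equipment, work productivity and
    leisure via the WPAI questionnaire), remission and QALY effect measures,
    multiple imputation of missing follow-up data with Rubin-rules pooling,
    stratified nonparametric bootstrap of incremental costs and effects,
    incremental cost-effectiveness ratios, cost-effectiveness planes and
    acceptability curves, one-way cost-driver sensitivity scenarios, and a
    calibrated synthetic three-arm trial generator for fully reproducible
    testing without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
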