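Package: caseonly
Title: Case-Only Analysis of Biomarker-Treatment Interactions in Small
    Survival Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation framework and penalized estimators for evaluating
    predictive biomarker-treatment interactions in small survival studies.
    Generates cohorts with a controlled marker-treatment odds ratio and
    exponential or Weibull event times; fits the case-only logistic model
    with risk-set offsets, with and without Firth's bias-eliminating
    penalization, and the full-cohort Firth-penalized Cox comparator, both
    with Wald and profile-likelihood confidence intervals; and computes
    bias, empirical and model-based standard errors, coverage and power
    over replicated scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    survival,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
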