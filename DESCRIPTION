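Package: ccscreen
Title: Cervical Cancer Screening Coverage Trends, Re-Screening and
    Treatment Coverage in Sub-Saharan Africa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation pipeline for trends in cervical cancer screening
    coverage among women in sub-Saharan Africa. Provides a four-level
    Bayesian multilevel binomial logistic regression of lifetime and
    past 3-year screening with HIV-serostatus marginalization for
    surveys that do not report serostatus, post-stratification of
    posterior coverage draws to population aggregates with imputation
    for countries without surveys, a multistate (never/once/twice+)
    life table of re-screening by age 45 driven by a rate ratio
    identified from cross-sectional age increments, and a Bayesian
    random-effects meta-analysis of cervical pre-cancer treatment
    coverage. Includes a synthetic-data generator with known ground
    truth so that every stage of the pipeline can be validated by
    parameter recovery, microsimulation oracles and posterior
    predictive checks. Models are fit with JAGS via rjags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
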