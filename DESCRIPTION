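Package: plasmatch
Title: Plasmode Simulation for Propensity Score Matching Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plasmode simulation framework for benchmarking propensity score
    estimation methods under 1:1 caliper matching with a doubly adjusted
    outcome model. Generates a realistic critical-care style cohort (or loads
    a real cohort CSV), builds a complex true outcome-generating model with
    polynomial, interaction and transcendental covariate terms, resamples
    covariate/exposure rows while simulating outcomes from the known model,
    and compares logistic regression, multivariate adaptive regression
    splines (MARS), supervised deep learning and autoencoder propensity
    scores on bias, empirical and model-based standard errors, mean squared
    error, coverage and bias-eliminated coverage with Monte Carlo standard
    errors. Includes a targeted maximum likelihood estimation (TMLE)
    comparator with a two-learner super learner, greedy nearest-neighbour
    caliper matching with standardized mean difference diagnostics, and
    zip-plot data export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    pracma,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
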