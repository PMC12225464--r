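Package: patroldetect
Title: Conditional Bayesian Models of Violation Occurrence and
    Detectability in Enforcement Patrol Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing enforcement-patrol records of illegal
    fishing (and similar compliance-monitoring data) with a conditional
    Bayesian hierarchical model: a violation submodel for the probability
    that a violation is present when a patrol takes place, and a detection
    submodel for the probability that the patrol detects it, linked
    through a two-stage Bernoulli observation process. Includes a
    synthetic-data generator that simulates patrol records from known
    ground-truth parameters, an adaptive Metropolis sampler over
    box-constrained uniform priors, split-chain Gelman-Rubin convergence
    diagnostics, WAIC model comparison, posterior-predictive
    classification with an F1-optimal threshold sweep, and posterior
    reporting of per-category log-odds ratios, annual detectability
    series, and headline probability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
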