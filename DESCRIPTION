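Package: gentapk
Title: Population Pharmacokinetics and Once-Daily Dose Optimization of
    Gentamicin in Pediatrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for pediatric gentamicin population pharmacokinetic
    analysis from sparse therapeutic drug monitoring (peak/trough) data:
    closed-form one- and two-compartment intravenous infusion models with
    multi-dose superposition and steady-state solutions, nonlinear
    mixed-effects estimation by Laplace approximation with stepwise
    covariate selection on a -2LL scale, nonparametric bootstrap and
    visual predictive checks, Monte Carlo simulation of probability of
    target attainment (Cmax/MIC) with trough-safety screening across
    pediatric age groups, and a calibrated synthetic cohort generator for
    sparse peak/trough sampling designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    jsonlite
Config/testthat/edition: 3
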