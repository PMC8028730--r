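Package: atropk
Title: Population Pharmacokinetics of Ophthalmic Atropine in Horses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of atropine plasma disposition in
    horses after intravenous bolus, topical eye-drop, and constant-rate
    subpalpebral ocular infusion. Implements closed-form two-compartment
    concentration-time solutions for the three input routes, Laplace-approximate
    marginal maximum likelihood with censored below-quantification (M3)
    observations, empirical Bayes post-hoc estimates with shrinkage diagnostics,
    conditional weighted residuals, visual predictive checks, nonparametric
    bootstrap precision intervals, and deterministic plus Monte Carlo simulation
    of topical dosing regimens. Includes a synthetic-study generator emulating a
    six-horse, three-occasion crossover design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
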