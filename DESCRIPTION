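Package: mctmm
Title: Minimal Continuous-Time Markov Models for Ordered Adverse-Event Grades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dose-toxicity modelling of longitudinal ordered adverse-event
    grades with a minimal continuous-time Markov model (mCTMM): a four-state
    Markov chain over severity grades 0-3 whose stationary distribution is a
    proportional-odds model and whose kinetics are governed by a single mean
    equilibration time. Provides marginal maximum-likelihood estimation with
    a Laplace approximation (adaptive Gauss-Hermite quadrature as a
    cross-check), likelihood-ratio covariate screening, non-parametric
    bootstrap, categorical visual predictive checks, simulation of
    grade-driven dose-adjustment policies, empirical-Bayes individual
    prediction, and a synthetic-cohort generator emulating a 150-patient
    capecitabine hand-foot syndrome study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
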