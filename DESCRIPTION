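Package: cpcausal
Title: Causal Treatment-Effect Estimation for Cerebral Palsy Gait Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates short-term average treatment effects on the treated
    (ATT) for common orthopedic and neurological treatments in ambulatory
    children and young adults with cerebral palsy, using three causal
    inference approaches on limb-level observational cohorts: optimal-subset
    direct matching on Mahalanobis rank distance with a propensity caliper
    and near-fine balance, virtual twins over a from-scratch Bayesian
    Additive Regression Trees (BART) engine, and Bayesian Causal Forests
    (BCF) with a prognostic and a treatment-moderating forest. Includes a
    seeded synthetic-cohort generator with targeted treatment selection and
    a four-level outcome causal chain (body structures, specific kinematic,
    overall kinematic, functional mobility), eligibility filtering,
    missing-data handling with an explicit "Miss" level, FAQt construction
    and imputation, covariate-balance diagnostics, limb-level bootstrap
    confidence intervals, and effect-size categorization and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    clue,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
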