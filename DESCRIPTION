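Package: rwdual
Title: Dual-Source Rescorla-Wagner Modelling of Probabilistic Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and model-based analysis of two-source probabilistic
    learning tasks in which a primary information stream (directly indicated
    by feedback) and a secondary stream (whose accuracy must be inferred)
    jointly guide binary choices. Implements pseudo-randomised reward
    schedules with stable and volatile phases, a dual-source Rescorla-Wagner
    model with phase-specific learning rates, an advice-weighted value
    combination and a unit-square-sigmoid response rule, a grid-based
    Bayesian learner that tracks reward probability and volatility,
    maximum-a-posteriori parameter estimation with Laplace model evidence,
    random-effects Bayesian model selection, parameter-recovery studies,
    optimal-learner regression weights and optimal-learning-rate analyses,
    and a synthetic cohort generator for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
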