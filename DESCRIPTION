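Package: hideseek
Title: Learning-Progress and Novelty Models of Curiosity-Driven Exploration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing exploration behaviour in a volatile
    hide-and-seek prediction task. Provides a generative simulator of
    per-character Gaussian hiding patterns with changepoint (hazard)
    dynamics, a reduced-Bayesian changepoint observer that converts
    trial-by-trial predictions into prediction error, learning progress,
    changepoint probability, adaptive learning rate, expected prediction
    error, expected learning progress and novelty, behavioural coding of
    leave-stay and exploratory choice decisions, logistic mixed-effects
    decision models with marginal effects and collinearity diagnostics,
    and a synthetic-cohort generator with known ground truth for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    methods,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    MASS,
    optparse
Config/testthat/edition: 3
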