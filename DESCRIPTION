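Package: coxvalsim
Title: Internal Validation Strategies for Penalized Cox Models on
    High-Dimensional Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation benchmark of internal-validation strategies
    (train-test split, conventional bootstrap, 0.632+ bootstrap, repeated
    K-fold cross-validation, repeated nested cross-validation) for
    elastic-net penalized Cox proportional-hazards models fitted to
    high-dimensional transcriptomic plus clinical covariates with
    right-censored time-to-event outcomes.  Includes a synthetic cohort
    generator (skewed transcript expression, clinical covariates, event
    times drawn by inverting the cumulative baseline hazard),
    inverse-probability-of-censoring-weighted discrimination and
    calibration metrics (cumulative/dynamic time-dependent AUC, Harrell's
    C-index, Brier score and integrated Brier score), oracle performance
    references, optimism-bias quantification, and scenario orchestration
    with variance-homogeneity testing across strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
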