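Package: imperfectbayes
Title: Bayesian and Heuristic Observer Models for Visual Search Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of target-detection
    behaviour in visual search displays with mixed cue reliability.
    Implements the optimal (ideal) Bayesian observer for a four-item
    detection task, imperfect variants with late decision noise, an
    ignorant (reliability-blind) Bayesian, heuristic decision rules
    (max, minimum deviation, Minkowski distance, mean, variance) and a
    posterior-sampling observer. Provides Monte-Carlo marginal
    likelihoods with common random numbers, prior-constrained
    maximum-likelihood fitting, AIC and cross-validated model
    comparison, model-recovery analysis, sensitivity (d-prime) based
    optimality indices with a sensory/computational loss decomposition,
    psychometric calibration of per-subject task parameters, and
    simulations of specific computational imperfections in the optimal
    decision variable.
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
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
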