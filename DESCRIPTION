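Package: earlitr
Title: Doubly Robust Learning of Individualized Treatment Rules with Convex
    Surrogate Losses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates optimal individualized treatment rules from
    observational data by minimizing a convex surrogate relaxation of the
    augmented inverse probability weighted (AIPW) value estimator over
    linear decision rules. The estimator is doubly robust: it is consistent
    for the optimal rule when either the propensity score model or the
    outcome regression model is correctly specified. Includes hinge,
    squared-hinge, logistic and exponential surrogate losses with their
    psi-transform risk-to-value maps, a K-fold sample-splitting variant
    with rule aggregation, cross-validated penalty selection by the
    normalized inverse-probability-weighted value, outcome weighted
    learning and Q-learning comparators, a permutation test for rule
    coefficients, and simulation scenario generators with analytic oracles
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
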