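Package: netlvm
Title: Network Versus Latent-Variable Models of Cognitive Test Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing regularized partial-correlation network models
    (Gaussian graphical models selected by graphical lasso with extended BIC)
    against confirmatory latent-variable models (correlated group factors,
    hierarchical, bifactor, and penta-factor structures) fitted by maximum
    likelihood to the same correlation matrices. Includes Fisher-z pooling of
    correlation tables, the partial-correlation transform, a coordinate-descent
    graphical lasso, a covariance-structure estimator with fixed-weight
    cross-sample validation, standard fit indices (chi-square, RMSEA, CFI,
    AIC), and a synthetic-data generator emulating a 15-subtest cognitive
    battery with a strong general factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
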