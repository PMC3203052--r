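Package: aldrf
Title: Receptive Field Estimation with Localized Priors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Empirical-Bayes and fully Bayesian estimation of linear
    receptive fields under hierarchical Gaussian priors that encode locality
    in spacetime and in spatiotemporal frequency (automatic locality
    determination: ALDs, ALDf and the sandwich-covariance ALDsf), together
    with the standard baselines (maximum likelihood / whitened STA, ridge
    regression, automatic relevance determination, automatic smoothness
    determination). Evidence and posteriors are computed from sufficient
    statistics with Woodbury-stable linear algebra; hyperparameters are
    optimized with analytic gradients or sampled with Metropolis-Hastings.
    Includes generators for simulated receptive fields (Gabor,
    difference-of-Gaussians, grid-cell, windowed noise), white and 1/F
    Gaussian stimulus ensembles, and the error metrics used to benchmark
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
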