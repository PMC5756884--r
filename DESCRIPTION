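Package: analogcast
Title: Hierarchical Bayesian Analog Forecasting for Spatiotemporal Count Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analog forecasting for space-time count fields cast as a fully
    hierarchical Bayesian model. Counts are reduced with an offset nonnegative
    matrix factorization (NNSVD-initialised multiplicative updates), a
    high-dimensional forcing field is reduced to coefficient series with
    empirical orthogonal functions or Laplacian eigenmaps, time-lagged
    embedding matrices of the coefficients are compared with a Procrustes
    distance to locate historical analogs, and a Poisson data model with a
    bias-corrected truncated-normal process model is fit by Metropolis-Hastings
    MCMC to produce posterior-predictive forecasts with full uncertainty.
    Includes a Poisson space-time (VAR on kernel principal component scores)
    baseline model, forecast scoring utilities, and synthetic-data generators
    with known analog structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
biocViews: Bayesian, TimeCourse, Spatial, DimensionReduction, Regression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
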