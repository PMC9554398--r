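Package: countqr
Title: Quantile Regression for Count Data via Jittering and Coefficient Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linear quantile regression with count responses. Implements
    the average-jittering estimator (uniform noise addition, linear or logarithmic
    transforms, ceiling-based recovery of count quantiles, bootstrap standard
    errors) and the quantile-regression-coefficients-modelling (QRCM) estimator, in
    which every regression coefficient is a parametric function of the quantile
    order built from shifted Legendre polynomials and logarithmic terms and all
    parameters are estimated jointly by minimising an integrated pinball loss.
    Includes M-estimation covariance and global Wald tests, probability-integral-
    transform goodness-of-fit tests with Monte Carlo p-values, a model-selection
    grid, a synthetic generator for university-credit-style count data, and an
    end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
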