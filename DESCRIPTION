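Package: sockidx
Title: Spatio-Temporal Index Standardization for Juvenile Sockeye Salmon
    Trawl Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a Poisson-link delta generalized linear mixed model with
    spatial and spatio-temporal Gaussian random fields (Matern correlation
    on a k-means knot mesh, Laplace-approximated marginal likelihood via
    'TMB') to station-level trawl-survey catches, and derives annual
    abundance indices, centers of gravity, and effective area occupied
    with simulation-based retransformation-bias correction.  Includes
    B-spline and linear density covariate effects with percent-deviance
    explained comparisons, stomach-content-index diet summaries,
    second-order polynomial trend regressions among annual indices, a
    synthetic trawl-survey generator for end-to-end testing, and a
    configurable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    TMB,
    Matrix,
    stats,
    splines,
    utils,
    jsonlite,
    yaml
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    statmod
Config/testthat/edition: 3
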