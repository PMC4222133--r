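Package: spmaging
Title: Stochastic Process Models of Aging for Joint Longitudinal and
    Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, maximum-likelihood estimation, and forecasting
    for stochastic process models (quadratic hazard models) of aging, in
    which physiological biomarkers follow a mean-reverting diffusion and
    the mortality or incidence hazard is a quadratic function of the
    deviation of the biomarker from an age-dependent physiological norm.
    Includes the latent-class extension (finite mixture of model regimes
    with multinomial-logistic class membership) and the genetic extension
    for cohorts in which only a sub-sample is genotyped, dynamic
    individual prediction of conditional survival, and microsimulation
    forecasting under what-if intervention scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
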