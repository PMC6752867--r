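Package: prepaid
Title: Prepaid Likelihood-Free Parameter Estimation
Version: 0.1.0
Authors@R: person("Prepaid", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Likelihood-free parameter estimation from a precomputed
    ("prepaid") database of simulated summary statistics. A bounded
    parameter space is charted once with quasi-random (Halton) points;
    at each point long simulations are compressed into summary-statistic
    means, per-length covariance matrices and raw sample banks. Any
    observed data set is then estimated in seconds by nearest-neighbour
    synthetic likelihood, local surrogate interpolation (least-squares
    support vector machines) with differential-evolution optimization,
    or grid-based approximate Bayesian computation, including priors,
    cross-condition equality constraints and bootstrap confidence
    intervals. Ships simulators and summary statistics for the Ricker
    population model, a trait-based stochastic community model and an
    analytic toy-normal study, plus a recovery/coverage study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
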