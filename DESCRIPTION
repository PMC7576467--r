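Package: hftelesim
Title: Cost-Utility Microsimulation of Heart Failure Telemonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level state-transition (first-order Monte Carlo)
    microsimulation for cost-utility analysis of a nurse-led heart failure
    telemonitoring program against standard ambulatory care, from the public
    payer perspective. Generates correlated virtual patient cohorts from
    published marginal moments via a Gaussian copula (Cholesky) sampler,
    assigns per-patient lifetime mortality through a Seattle Heart Failure
    Model style proportional-hazards score, and simulates monthly cycles
    through seven health states (four NYHA classes, index hospitalization,
    readmission, death) under common random numbers across arms. Produces
    discounted costs and QALYs, incremental cost-effectiveness ratios with
    Monte Carlo standard errors, probabilistic sensitivity analysis with
    gamma, beta, Dirichlet and log-normal parameter sampling,
    cost-effectiveness acceptability curves, and NYHA-class, deployment-mix
    and one-way effectiveness scenarios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils,
    Matrix,
    fitdistrplus,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
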