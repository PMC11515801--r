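Package: swctsim
Title: Simulation and Robust Analysis of Stepped-Wedge Cluster Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating cross-sectional stepped-wedge cluster
    trials (SW-CTs) with continuous outcomes and for comparing analytic
    models in Monte Carlo studies. Generates staircase designs with one
    cluster per sequence, gamma-Poisson cluster-period sample sizes, and
    cluster-level covariate imbalance or confounding. Fits the
    Hussey-Hughes mixed-effects model by restricted maximum likelihood
    with block-exchangeable generalized least squares, with Satterthwaite
    and Kenward-Roger small-sample corrections, and the within-cluster
    fixed-effects model by ordinary least squares. Estimates the
    intracluster correlation coefficient in a separate step from the
    treatment-effect analysis, and summarises operating characteristics
    (bias, precision, power, type I error, coverage, RMSE, Monte Carlo
    standard error) over replicated simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    MASS,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
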