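Package: gpgrowth
Title: Multi-Task Gaussian Process Mixtures for Childhood BMI Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, clusters and prospectively forecasts childhood body mass
    index (BMI) trajectories with a multi-task Gaussian process mixture: K
    cluster-specific mean processes shared across children, per-child smooth GP
    deviations and i.i.d. measurement noise, trained by variational EM. Includes
    reference methods (per-child cubic smoothing splines and the hierarchical
    Jenss-Bayley nonlinear mixed-effects growth model), a seeded synthetic
    cohort generator with ground-truth accessors, evaluation designs for
    missing-data reconstruction and age-threshold forecasting (MSE and weighted
    95% credible-interval coverage), and a posterior-sampling calculator for
    the probability of crossing sex-specific overweight/obesity BMI cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
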