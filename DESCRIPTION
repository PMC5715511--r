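Package: jointmsm
Title: Marginal Structural Cox Models for Two Concurrent Time-Varying
    Treatments
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation machinery for joint marginal
    structural Cox models (Cox-MSM) with two monotone time-varying
    treatments and a treatment-treatment interaction. Generates
    longitudinal cohorts with a CD4-like time-dependent confounder that
    both predicts treatment initiation and is affected by past treatment,
    estimates stabilized inverse-probability-of-treatment weights by
    pooled logistic regression, fits weighted Cox models with
    cluster-robust variance on counting-process data, and evaluates
    bias, RMSE and confidence-interval coverage of weighted versus
    unweighted estimators over a grid of confounding and effect-size
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
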