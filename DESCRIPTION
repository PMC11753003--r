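Package: crtperm
Title: Covariate-Constrained Randomization and Permutation Tests for
    Cluster-Randomized Trials with Time-to-Event Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis tools for two-arm cluster-randomized trials
    with censored time-to-event outcomes. Simulates clustered exponential
    survival data with cluster-level covariates and gamma frailties, performs
    covariate-constrained randomization via an inverse-variance imbalance
    score or per-covariate ratio bounds, and analyzes trials with three
    methods: a Cox proportional-hazards model with a cluster-robust (Huber
    sandwich) variance, a mixed-effects (Gaussian random-intercept) Cox
    model, and a permutation test based on cluster means of deviance
    residuals whose reference distribution is the (constrained) randomization
    space actually used in the design. A Monte-Carlo engine estimates type I
    error and power with Monte-Carlo standard errors across scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
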