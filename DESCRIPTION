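Package: seqiptw
Title: Sequential Stabilized Inverse Probability Weighting for Phase-Specific
    Effects in Multiphase Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the causal effect of a single downstream treatment phase
    of a multiphase randomized trial under differential compliance. Fits
    sequential logistic propensity models for each selection step (e.g.
    transplantation, then consolidation), combines stabilized inverse
    probability of treatment weights across phases, and analyses
    progression-free survival with weighted Kaplan-Meier curves, a weighted
    log-rank test, weighted Aalen additive hazards diagnostics for time-varying
    effects, and a weighted Cox model with episode splitting at a changepoint
    and Lin-Wei robust sandwich variance. Includes a synthetic multiphase-trial
    generator with configurable covariate prevalences, selection coefficients
    and a piecewise-constant treatment effect on the hazard, so the whole
    pipeline can be exercised and validated without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
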