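Package: effortpain
Title: Simulation and Hierarchical Bayesian Modelling of a Pain-Avoidance
    Prosocial Effort Task
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse a binary-choice prosocial effort
    task in which participants trade physical effort against electric-shock
    reduction for themselves or another person. Provides pseudo-randomized
    trial-schedule generation, effort-discounting subjective-value models
    (linear, parabolic, hyperbolic) with a softmax choice rule, synthetic
    agent cohorts, hierarchical Bayesian estimation with self/other effect
    coding via a built-in No-U-Turn sampler, model comparison by
    Pareto-smoothed importance-sampling leave-one-out cross-validation
    (PSIS-LOO), posterior predictive checks and parameter recovery, and
    default-prior Bayes factors for behavioural null effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
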