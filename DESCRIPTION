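Package: habitlearn
Title: Simulation and Model-Based Analysis of Outcome Devaluation in the
    Two-Step Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative simulation and analysis of sequential two-step
    decision tasks with post-training outcome devaluation. Provides the
    task environment (drifting Gaussian-random-walk reward probabilities
    with reflecting bounds, common/rare transitions, devaluation and
    consumption phases), hybrid model-based/model-free reinforcement
    learning agents with softmax choice and perseveration, subject-level
    devaluation and consumption sensitivity scores with quality-control
    exclusion filters, trial-lagged stay-probability logistic regressions
    with a between-subject devaluation moderator (mixed-effects and
    two-stage engines), likelihood-based estimation of the hybrid agent
    by per-subject maximum likelihood and hierarchical Bayesian MCMC with
    a group-level slope of the model-based weight on devaluation
    sensitivity, and a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    metafor,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
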