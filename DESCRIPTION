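Package: arbrl
Title: Arbitration Control of Model-Based and Model-Free Reinforcement
    Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, maximum-likelihood fitting, and model comparison
    for dynamic arbitration between a model-based (FORWARD) and a
    model-free (SARSA) reinforcement learner in a two-stage Markov
    decision task with goal and transition-uncertainty manipulations.
    Implements reliability estimation for both systems (empirical-Bayes
    dispersion of state prediction errors; Pearce-Hall associability of
    reward prediction errors), a two-state model-choice-probability
    dynamic, reliability-weighted softmax exploitation, multi-start
    Nelder-Mead fitting with BIC and group Bayes factors, model-free
    behavioural measures (accumulated reward, choice optimality, choice
    consistency), parameter/model/behaviour recovery analyses, and a
    synthetic cohort generator in which a depression score (CES-D)
    modulates model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
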