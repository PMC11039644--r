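Package: revlearn
Title: Probabilistic Reversal Learning: Simulation, Hierarchical
    Q-Learning Model Fitting and Group Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for within-subject pharmacological studies of
    probabilistic reversal learning. Simulates the task (dependent 80/20
    reward contingencies, a 5-of-6 learning criterion arming a 20%
    per-trial reversal hazard) and cohorts of Q-learning agents; fits a
    factorial family of eight Rescorla-Wagner model variants with
    separate reward and punishment sensitivities by hierarchical
    expectation-maximization with Laplace-approximated subject
    evidences; compares models by random-effects Bayesian model
    selection with exceedance probabilities; computes the model-free
    behavioral battery (percent correct, switches, reversals, paired
    tests, win/loss switch analysis); and exports trial-by-trial
    prediction errors as parametric-modulator event files for
    neuroimaging first-level models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
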