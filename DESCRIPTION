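Package: flexmb
Title: Model-Based and Model-Free Control in a Two-Level Contingency-Change Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a two-level sequential
    decision task in which the transition contingencies between second-level
    and terminal states flip every few trials. Provides the task environment
    (contingency-flip scheduling, a bounded Gaussian reward random walk, and
    periodic reward-assignment swaps), model-free TD(lambda), model-based, and
    hybrid reinforcement-learning agents with fictive (mirrored) updates,
    stay-probability behavioural analyses, hierarchical expectation-maximization
    model fitting with Gaussian group priors, model comparison via the
    integrated Bayesian information criterion and exceedance probabilities,
    parameter-recovery pipelines, and permutation tests for block-wise and
    frequency-wise differences in the model-based weight.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
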