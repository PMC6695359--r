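Package: stgtsim
Title: Dual-System Reinforcement-Learning Simulation of Sign- and
    Goal-Tracking in Pavlovian Autoshaping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates conditioned approach behaviour (sign-tracking towards
    a reward-predictive lever versus goal-tracking towards the food magazine)
    in a Pavlovian autoshaping task, using a hybrid agent that combines a
    Feature-Model-Free temporal-difference learner over environmental
    features with a Model-Based learner of task structure. Provides the
    deterministic task graphs (including a split conditioned-stimulus
    variant with two decision points per cue presentation), softmax action
    selection, inter-trial-interval value revision, population simulation
    over individual model-based/model-free weightings, tidy per-trial logs
    of choices and reward-prediction errors, behavioural scores, and the
    accompanying statistical battery (repeated-measures ANOVA, Welch and
    paired t tests, Wilcoxon signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
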