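Package: dualcontrol
Title: Dual-System Reinforcement Learning: Two-Step and Devaluation Task
    Simulation and Hierarchical Model Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulators and analysis tools for the two experimental
    paradigms used to dissociate goal-directed (model-based) from habitual
    (model-free) instrumental control: the two-step sequential
    decision-making task and the selective outcome-devaluation paradigm.
    Implements the seven-parameter hybrid SARSA(lambda) / model-based
    reinforcement-learning model with softmax choice and perseveration,
    hierarchical empirical-Bayes parameter estimation (per-subject MAP with
    Laplace-approximate variances, EM updates of a Gaussian group prior),
    model-agnostic behavioral statistics (stay-probability tables, 2x2
    within-subject contrasts, interaction scores, one-tailed Spearman
    correlation with exact small-n permutation p-values), and a synthetic
    cohort generator with a latent goal-directedness trait coupling the two
    tasks for end-to-end construct-validity analyses.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
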