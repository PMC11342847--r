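Package: cvarlearn
Title: Distributional Value Learning and Risk Sensitivity in Card-Deck Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pro-variance bias (risk seeking) in magnitude
    learning. Implements a card-deck two-option task with full feedback in
    which deck value distributions vary in mean and variance, four
    trial-by-trial learning models (Rescorla-Wagner with one or two learning
    rates, the PEIRS value-plus-spread model, and a Bayesian learner with a
    Conditional Value at Risk readout), parameter-sweep simulations,
    per-subject maximum-likelihood fitting with BIC model comparison and
    parameter recovery, and a model-free analysis stage (exclusion rules,
    choice rates, pro-variance bias, trait correlations). Includes a
    synthetic-cohort generator with a planted trait-parameter link so the
    whole pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
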