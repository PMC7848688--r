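Package: creditmap
Title: Cognitive-Map-Guided Credit Assignment in Dual-Outcome Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulator, hybrid model-based/model-free reinforcement
    learning agent, and analysis pipeline for a full-feedback dual-outcome
    bandit task in which four bandits ("persons") each lead to a unique pair of
    four probabilistic outcomes ("vegetables") whose reward probabilities drift
    as reflected Gaussian random walks. Implements outcome-type-specific credit
    assignment (Common, Exclusive, Counterfactual, Absent) in both the
    model-free and model-based systems, per-subject maximum-likelihood fitting
    with analytic gradients, bootstrap generalized-likelihood-ratio tests of
    nested submodels, random-effects Bayesian model selection with protected
    exceedance probabilities, Bayesian model averaging of parameters,
    model-agnostic choice-repetition and side-choice regression signatures, an
    ideal Bayesian observer benchmark, and standardized-earnings simulations
    over grids of credit-assignment regimes, including an
    importance-autocorrelated task variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    lmerTest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
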