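Package: lungbn
Title: Bayesian Networks for Survival Prediction and Treatment
    Recommendation in Lung Cancer Registries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discrete Bayesian-network tooling for clinical decision support
    with registry-style lung cancer data: K2/Bayesian scoring, structure
    learning (K2 ordering search, simulated annealing, MCMC, tree-augmented
    naive Bayes, constraint-based discovery, and expert-prior-constrained
    search with temporal tiers), exact inference with evidence, do-operator
    causal interventions on the treatment variable, stratified
    cross-validation with AUC/accuracy reporting, survival-maximising
    treatment recommendation with exact/partial concordance analysis, and a
    calibrated synthetic cohort generator with informative (NMAR)
    missingness for end-to-end testing without access to the registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
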