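Package: molforge
Title: Multi-Objective De Novo Molecular Design with Recurrent SMILES Generators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo small-molecule design around a stacked-LSTM SMILES language
    model with multi-head self-attention, trained by policy-gradient
    reinforcement learning against random-forest QSAR activity predictors.
    Rewards for several pharmacological objectives (for example high adenosine
    A1/A2A receptor affinity with low hERG liability) are combined either by an
    adaptive weighted sum or by Pareto non-dominated sorting with a
    diversity-aware rank-to-reward map. Sampling during reinforcement learning
    is diversified by evolutionary crossover and mutation between an agent, a
    crossover and a frozen prior network, with roulette-wheel selection of the
    fittest molecules. Includes SMILES standardization and tokenization,
    ECFP6/descriptor featurization, and deterministic synthetic-data generators
    so the whole pipeline runs and is testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ChemmineR,
    ChemmineOB,
    ranger,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
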