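Package: hipporpe
Title: Hippocampal-Subfield Network Simulation of Rule-Plus-Exception
    Category Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Shepard Type III rule-plus-exception category
    learning with a rate-coded autoencoder network of the hippocampal
    circuit (EC_in, DG, CA3, CA1, EC_out; trisynaptic and monosynaptic
    pathways with big-loop recurrence), trained on early- versus
    delayed-exception 144-trial sequences.  Provides the Luce-choice
    accuracy readout from the output layer's category units,
    representational similarity analysis of the hidden subfields, the
    category representational difference (CRD) statistic with rank-sum
    condition comparisons, Sammon mappings with Procrustes-aligned
    learning trajectories, mixed-effects analyses of model and
    behavioural accuracy, and a synthetic behavioural-data generator for
    testing the preprocessing and model-fitting stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
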