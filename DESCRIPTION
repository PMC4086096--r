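Package: ddidock
Title: Drug-Drug Interaction Prediction from Chemical-Protein Interactome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) from chemical-protein
    interactome (CPI) profiles, i.e. matrices of reverse-docking scores of
    drug molecules against a panel of pharmacokinetic and pharmacodynamic
    protein structures. For every unordered drug pair the per-target sum and
    absolute difference of the two docking-score vectors form a symmetric
    feature vector; an L2-regularized logistic regression classifier is
    trained on known interacting pairs versus sampled non-interacting pairs
    and evaluated with repeated stratified cross-validation, maximum-F1
    threshold selection and an independent hold-out protocol. Includes
    AutoDock-Vina result parsing, per-target rank-percentile readouts for
    mechanistic interpretation, a Tanimoto-coefficient redundancy filter,
    and a planted-model synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
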