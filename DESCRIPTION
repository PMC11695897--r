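Package: dephos
Title: Hybrid-Learning Prediction of Phosphatase-Specific Dephosphorylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts general and phosphatase-specific dephosphorylation sites on
    protein sequences with a stacked hybrid-learning framework. Peptide windows
    around candidate serine, threonine and tyrosine residues are encoded with ten
    sequence features (including a substitution-matrix peptide-similarity score),
    scored by penalized logistic regression, feed-forward neural networks and two
    small transformer networks, and integrated by a logistic meta-learner over the
    22-score stacking vector. A three-step cascade pretrains on general
    phosphorylation, fine-tunes to general dephosphorylation, and derives
    phosphatase-specific predictors by transfer learning (data-rich phosphatase
    clusters) or first-order model-agnostic meta-learning (few-shot clusters).
    Includes cross-validation and specificity evaluation, Shapley-value sequence
    attribution with correlation-filtered motif discovery and enrichment against
    curated dephosphorylation motifs, and a synthetic proteome generator with
    planted motifs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    Biostrings,
    glmnet,
    seqinr,
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
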