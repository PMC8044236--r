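Package: mutafuse
Title: Weight-of-Evidence Fusion Models for Mutagenicity QSAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR)
    classifiers for compound mutagenicity from heterogeneous genotoxicity
    assay panels. Raw assay records are integrated into the three ICH
    S2(R1) weight-of-evidence endpoint groups (bacterial reverse mutation;
    in vivo mammalian cytogenetics; in vitro and germ-cell assays) by
    majority voting with ties resolved positive. Molecular structure is
    described by 881-bit PubChem substructure fingerprints in the
    PaDEL-Descriptor CSV dialect. Features are selected by intersecting
    the first quintile of per-endpoint SHAP importance rankings; random
    forest, support vector machine and feed-forward neural sub-models are
    tuned by grid search under stratified five-fold cross-validation; and
    the three per-endpoint sub-models of each algorithm are fused by the
    weight-of-evidence rule (all-negative is negative, otherwise
    positive), with a noisy-OR score for ROC analysis. Includes a
    synthetic compound-panel generator with planted informative bits for
    end-to-end testing, and the full evaluation suite (accuracy, per-class
    precision/recall/F1, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    ggplot2,
    jsonlite,
    nnet,
    ranger,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
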