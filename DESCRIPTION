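Package: npxhier
Title: Two-Stage Hierarchical Multi-Disease Classification of Plasma Proteomic NPX Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Knowledge-guided two-stage hierarchical classification of multi-disease
    plasma proteomics cohorts measured in Normalized Protein eXpression (NPX, log2)
    units. A first-stage classifier separates broad disease categories defined by a
    clinical taxonomy (e.g. blood, psychiatric, metabolic, tumor, plus a terminal
    healthy class); per-category second-stage classifiers resolve the specific
    phenotype, and the two stages combine into a full multiclass probability vector.
    Includes borderline-SMOTE oversampling for imbalanced classes, permutation
    feature importance with cross-disease stacking, binary-restriction AUROC with
    the DeLong test for correlated ROC curves, Welch tests with Bonferroni
    correction, stratified performance audits, a healthy-subsampling sensitivity
    analysis, and a synthetic NPX cohort generator with planted category- and
    disease-level effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nnet,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
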