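Package: mtqsar
Title: Multitarget QSAR and Proteochemometric Modelling of
    Chemical-Protein Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Curates bioactivity records into balanced per-target binary
    classification sets (salt stripping, pIC50 labelling, deduplication),
    trains a named suite of fingerprint and proteochemometric classifiers
    (random forest, k-nearest neighbours, support vector machine and a
    single-hidden-layer neural network over MACCS keys and circular count
    fingerprints concatenated with reduced protein sequence descriptors),
    evaluates them by stratified hold-out and k-fold cross-validation with
    sensitivity, specificity, accuracy, Matthews correlation and ROC AUC,
    and calls chemical-protein interactions by a multivoting ensemble with
    a calibrated vote cutoff, exporting compound-target interaction
    networks.  Ships a synthetic chemogenomics benchmark generator with
    planted structure-activity signal for end-to-end testing without
    external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Biostrings,
    randomForest,
    e1071,
    caret,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
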