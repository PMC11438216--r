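Package: mvsynergy
Title: Multi-View Ensemble Prediction of Drug Combination Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the synergy of anticancer drug pairs on cancer cell
    lines from a multi-view ensemble. Four drug representations (2D
    chemical descriptors, a multi-view molecular-graph embedding, MACCS
    structural keys, and a binary drug-target vector) are crossed with
    four cell-line omics views (gene expression, copy number, mutation,
    proteomics, each compressed to a fixed width by a variational
    autoencoder). Each of the sixteen pairings feeds a shared multi-task
    network -- per-entity encoders, task-specific multi-head attention,
    a cross-stitch unit and two prediction heads -- that jointly emits a
    continuous Loewe synergy score and a three-class synergy label; the
    sixteen predictions are averaged into the final answer. Includes
    drug-pair-disjoint cross-validation, regression and classification
    metrics with fold-level aggregation, and a seeded synthetic-fixture
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH (used for SMILES parsing, MACCS keys and 2D
    descriptors)
Config/testthat/edition: 3
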