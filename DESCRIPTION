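Package: paratope
Title: Sequence-Based Antibody Paratope Prediction and Interface Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting and analysing antibody paratopes. Generates
    ground-truth paratope and epitope labels from antibody-antigen complex
    structures under the 4.5 Angstrom heavy-atom contact criterion, embeds
    antibody sequences through pluggable per-residue embedding backends
    (including a deterministic synthetic backend with an optional planted
    signal), trains a multilayer-perceptron residue classifier with input
    masking, dropout and early stopping on validation precision-recall AUC,
    evaluates predictions per protein (PR AUC, ROC AUC, F1, MCC), quantifies
    two-arm paratope and epitope asymmetry (Jaccard distance) with an
    arm-vs-arm prediction upper bound, pools sequence embeddings weighted by
    paratope probability, combines region-restricted and full-length
    probability tracks, and attributes predictions to embedding backends with
    Shapley values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
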