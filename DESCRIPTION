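Package: ppisae
Title: Sequence-Based Protein-Protein Interaction Prediction with Stacked Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions from amino-acid sequence
    alone. Protein pairs are encoded with autocovariance (AC) descriptors over
    seven physicochemical properties or with conjoint-triad (CT) counts over a
    seven-group amino-acid alphabet, and classified by a stacked autoencoder
    trained with greedy layer-wise pretraining followed by supervised
    fine-tuning through a softmax head. Includes tools to build benchmark-style
    datasets (length and residue filtering, cross-compartment negative
    sampling, hold-out splits, identity-based redundancy removal), a stratified
    k-fold cross-validation harness with confusion-matrix metrics, and a
    synthetic-data generator that plants a tunable motif-based interaction
    signal so the full pipeline can be exercised and calibrated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
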