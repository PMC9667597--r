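Package: ddiscl
Title: Multi-Type Drug-Drug Interaction Prediction with Supervised
    Contrastive Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the pharmacological type of drug-drug interactions
    (DDIs) from per-drug binary descriptors (chemical substructures,
    targets, enzymes, pathways). Drugs are represented by Jaccard
    similarity profiles against the whole drug set, encoded by a
    multi-head self-attention autoencoder, fused pairwise at multiple
    scales, and classified under a three-level loss combining
    reconstruction error, supervised contrastive learning, and a
    scheduled cross-entropy/focal classification loss. Includes the
    three cross-validation schemes for known-drug and cold-start
    evaluation, a six-metric report, and a synthetic-data generator
    with planted, recoverable class structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
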