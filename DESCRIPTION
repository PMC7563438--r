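Package: dietnets
Title: Parameter-Reduced Fully-Connected Networks for Somatic Mutation
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classify tumor samples from high-dimensional binary somatic
    mutation profiles with fully-connected networks whose first-layer
    ("fat") weights are predicted by an auxiliary network applied to the
    transposed data matrix (Diet Networks), optionally extended with a
    learnable element-wise input scaling vector under an L1 sparsity
    penalty.  Includes MAF-style mutation table ingestion with
    binarization and mutation-count gene ordering, equal-fold
    cross-validation, a synthetic cohort generator with planted
    class-associated genes, and interpretability tools: per-gene hidden
    representations, PCA-based low-rank approximation of the trained
    encoder, per-gene dominance t-tests, and principal-component gene
    rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    Rtsne,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
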