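Package: scscc
Title: Contrastive Clustering of Single-Cell RNA-Seq Data with Swapped
    Prototype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters single-cell RNA-seq count matrices by learning
    clustering-friendly cell embeddings with a small fully-connected
    encoder trained under two self-supervised objectives: an InfoNCE
    instance-contrastive loss over paired masked-and-noised views of each
    cell, and a swapped-prediction loss over learnable cluster prototypes
    whose targets are balanced with the Sinkhorn-Knopp algorithm. Final
    cell labels come from K-means on the learned embedding. Includes
    standard scRNA-seq preprocessing (filtering, median-library-size
    log-normalization, highly-variable-gene selection, per-gene
    standardization), clustering validity indices (adjusted Rand index,
    normalized mutual information, silhouette, Davies-Bouldin), a
    negative-binomial-with-dropout synthetic data generator, and readers
    for dense CSV/TSV and MatrixMarket count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
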