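Package: dcrelm
Title: Dual Correlation Reduction Deep Clustering for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deep embedded clustering of single-cell RNA sequencing expression
    matrices. Cells are mapped into a dense low-dimensional space by a frozen
    extreme-learning-machine random projection, two distorted views are built by
    Gaussian feature corruption and graph distortion (similarity-based edge
    masking and personalized-PageRank diffusion), and a fused attribute/graph
    autoencoder is trained with dual sample- and feature-level
    correlation-reduction losses and a triplet Student-t self-supervised
    clustering objective. Includes loaders for Matrix Market, delimited text and
    AnnData inputs, a zero-inflated negative-binomial simulator with known cell
    labels, clustering metrics (NMI, ARI, Hungarian-matched F1), and
    dropout-robustness and ablation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
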