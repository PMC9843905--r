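Package: pdalink
Title: Link Prediction for piRNA-Disease Associations via Projection
    Subgraphs and Graph Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts Piwi-interacting RNA (piRNA) to disease associations
    as a transductive link-prediction task on a heterogeneous graph.
    Intra-side piRNA-piRNA and disease-disease subgraphs are built by
    bipartite co-association projection restricted to nodes with PageRank
    centrality near the median; node features are derived from k-mer
    Jaccard, Gaussian interaction profile (GIP) kernel and MeSH-style
    semantic similarity profiles, augmented by residual scaling and
    compressed with a denoising autoencoder; a two-layer graph
    convolutional encoder with a fully-connected link predictor is trained
    end to end under a dual cross-entropy plus sensitivity-specificity
    loss. Includes synthetic fixture generators, cross-validation with
    negative sampling, leakage auditing, and metric reporting (AUC, AUPR,
    accuracy, precision, recall, F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
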