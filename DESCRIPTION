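Package: pnstage
Title: Stage-Resolved Single-Cell Transcriptomic Typing of Drosophila
    Olfactory Projection Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for stage-resolved single-cell RNA-seq analysis of
    developing Drosophila olfactory projection neurons: quality filtering and
    CPM normalization, overdispersed and iteratively-discovered marker gene
    selection, per-stage embedding and density- or graph-based clustering,
    one-vs-rest Mann-Whitney differential expression with Benjamini-Hochberg
    correction, cross-stage cluster matching by reciprocal-best Jaccard
    similarity of signature gene sets and by unique marker combinations,
    stage-wise transcriptomic diversity quantification with bootstrap
    confidence intervals, a permutation test for covariation of transcriptomic
    similarity with neuronal birth order, and grouping of globally dynamic
    genes by temporal profile. Includes a negative-binomial synthetic-data
    generator with planted ground truth emulating the statistical structure of
    a four-stage projection-neuron atlas, so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    matrixStats,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    FNN,
    Rtsne,
    uwot
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
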