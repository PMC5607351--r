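Package: mesclust
Title: Consensus Clustering and QC for Sorted Single-Cell RNA-Seq of Lung
    Mesenchyme
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible re-implementation of a SmartSeq2 single-cell
    RNA-seq analysis pipeline for FACS-sorted lung mesenchymal populations:
    six-criterion cell quality control, depth scaling by read resampling with
    robust regression, binned-dispersion highly-variable-gene selection,
    subsampled k-nearest-neighbour graph consensus clustering with Louvain
    community detection, and PCA/tSNE embedding. Ships a negative-binomial
    synthetic-data generator with planted cluster structure and engineered QC
    failures so every stage is testable without external downloads, plus the
    small closed-form quantifications used alongside such studies (delta-delta
    Ct qPCR fold change, colony-forming efficiency, clone-size distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    Matrix,
    Rtsne,
    cluster,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
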