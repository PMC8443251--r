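Package: svzlineage
Title: Dorsal and Ventral Neurogenic Lineage Analysis for V-SVZ Single-Cell RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing regionally distinct
    (dorsal versus ventral) neurogenic lineages in single-cell and
    single-nucleus RNA-seq of the ventricular-subventricular zone (V-SVZ).
    Implements cell-level quality control and sample-barcode demultiplexing
    with doublet flagging, log-normalization, PCA embedding and
    shared-nearest-neighbor Leiden clustering, module-score cell-cycle phase
    assignment, Wilcoxon rank-sum marker discovery with a
    fraction-expressing candidate filter, balanced-reference anchor-based
    regional label transfer with per-cell predicted-identity scores,
    rank-based gene-set AUC scoring with quartile High-Score selection and
    lineage-signature intersection, tree-ensemble gene-regulatory-network
    inference with marker-centered network construction and graph metrics,
    and in situ spot quantification along a normalized ventral-to-dorsal
    axis. A negative-binomial synthetic-data generator with known ground
    truth supports end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: SingleCell, RNASeq, Clustering, DifferentialExpression,
    NetworkInference, Spatial
RoxygenNote: 7.3.3
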