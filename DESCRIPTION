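Package: ifnregnet
Title: Regulatory Analysis of Interferon-Responsive Endothelial Gene Programs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline linking single-cell expression of
    interferon-stimulated gene (ISG) programs to accessible chromatin.
    Provides expression-bin-matched gene-set module scoring, QC filtering
    and Wilcoxon marker detection with Benjamini-Hochberg adjustment, a
    cluster-composition permutation test, position-weight-matrix scanning
    with exact p-value calibrated thresholds, a Normalized Motif Score
    (NMS) that weights per-peak motif counts by accessibility and peak
    length, and transcription-factor-family motif co-occurrence networks
    partitioned by leading-eigenvector spectral community detection. A
    synthetic-data module with planted ground truth exercises every stage
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
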