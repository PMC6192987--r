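Package: welldge
Title: Well-Barcoded 3' Digital Gene Expression Screening Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for plate-based, well-barcoded 3' counting
    RNA-seq compound screens. Simulates barcoded paired-end reads with exact
    per-molecule ground truth (PCR duplication, sequencing error, cross-well
    contamination, two-species barnyard plates, negative-binomial dose
    responses), demultiplexes well barcodes and UMIs into tagged reads,
    builds UMI-deduplicated wells-by-genes count matrices from transcriptome
    alignments, and provides the screening analytics: barnyard species
    purity, well correlation, gene-detection saturation, ROC benchmarking,
    CRISPR indel frame binning, potent-compound selection, quantile-normalized
    log2 fold-change feature matrices for mechanism-of-action clustering, and
    Fisher-Z random-effects meta-clustering across platforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    Biostrings,
    Rsamtools,
    limma,
    jsonlite,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    Rtsne,
    metafor,
    mclust,
    DESeq2,
    withr
Config/testthat/edition: 3
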