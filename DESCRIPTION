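Package: peakgrammar
Title: Differential ChIP-seq Peak Classes and Regulatory Motif Grammar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative regulatory genomics around the
    endothelial-to-hematopoietic transition: summit-centered ChIP-seq tag
    quantification and three-class (lost/shared/gained) peak classification
    by log2 signal fold change, nearest-TSS peak-to-gene annotation with
    hypergeometric overlap statistics, position-weight-matrix scanning,
    bootstrap Z-score co-occurrence analysis of footprinted motifs,
    oriented composite-motif spacing distributions, and integration with
    gene expression fold-change clustering. Includes a synthetic-landscape
    generator that plants ground-truth peak classes, motif co-occurrence
    and expression effects so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
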