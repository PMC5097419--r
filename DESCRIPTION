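Package: chipab
Title: Antibody Performance Metrics and Normalization for Paired-End ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality metrics and normalization utilities for comparing
    ChIP-seq antibodies from paired-end alignments. Implements insert-size-
    matched groupwise downsampling, fragment-length bias diagnostics against
    a seven-label genome segmentation, peak-base saturation curves,
    base-level sensitivity/specificity and peak overlap, SPOT (signal
    portion of tags) scoring, whole-cell-extract-relative region enrichment,
    binned genome coverage correlation, and replicate-level quality control,
    together with a synthetic fragment generator that emulates
    region-dependent shearing bias, mark-specific enrichment and
    replicate noise for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
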