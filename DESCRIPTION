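Package: bindwave
Title: Temporal Transcription-Factor Binding and Transcriptional Wave Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for timecourse ChIP-seq and mRNA-seq
    analysis of a master transcription factor's regulatory program:
    consensus binding-region calling from multi-caller peak sets with
    majority voting and gap-based merging, RPKM quantification with median
    normalization, target-gene assignment by distance rules, expression and
    differential-expression calling, target regulation classification,
    split-tree mining of transcriptional waves with time-varying
    TF-binding annotation, protein-binding-microarray 8-mer E-scores and
    alignment-based position frequency matrix construction, log-odds
    promoter scanning with hypergeometric enrichment, and hormone
    co-regulation network assembly. Ships a synthetic-data generator that
    emulates the statistical structure of an ethylene-response timecourse
    so the full pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    mclust,
    igraph,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
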