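Package: ejclip
Title: Transcriptome-Wide Analysis of Exon Junction Complex iCLIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for individual-nucleotide-resolution CLIP (iCLIP) analysis
    of exon junction complex (EJC) proteins: conversion of aligned reads to
    single-nucleotide crosslink events with random-barcode (UMI)
    deduplication, permutation-based peak calling with false discovery rate
    control within gene segments, positional 5mer motif enrichment against
    shuffled nulls, integration of per-protein peaks into high-confidence
    multi-protein EJC deposition sites, seven-category exon classification,
    exon- and junction-anchored coverage profiling, discovery of
    non-annotated candidate exons carrying splice donor motifs, and the
    accompanying enrichment statistics. Includes a synthetic transcriptome
    and iCLIP simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'annotation-io.R'
    'annotation.R'
    'crosslinks.R'
    'ejclip-package.R'
    'peakcalling.R'
    'motifs.R'
    'stats.R'
    'profiles.R'
    'sites.R'
    'simulate.R'
    'pipeline.R'
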