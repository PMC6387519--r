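Package: ssrscape
Title: Comparative Microsatellite Landscapes Across Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and comparative analysis of perfect microsatellites
    (SSRs, 1-6 nt motifs, >= 12 bp) across genome assemblies. Enumerates the
    501 canonical repeat classes obtained by collapsing primitive motifs under
    cyclic rotation and reverse complement, scans FASTA sequences exhaustively
    for maximal perfect repeats, computes per-genome frequency, base coverage,
    density and GC attributes, builds rank-based enrichment score matrices
    across organism cohorts with clade-signature tests, detects repeat-length
    preference peaks in unit-length histograms, annotates repeats against GFF3
    gene models (exon/intron/intergenic, nearest TSS), and generates synthetic
    genomes and cohorts with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    broom,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
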