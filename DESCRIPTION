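Package: annotaudit
Title: Auditing mRNA 5'-End Annotations with Long Reads, CAGE, smFISH and
    Polysome qPCR
Version: 0.1.0
Authors@R:
    person("annotaudit", "developers", email = "annotaudit@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for auditing mRNA 5'-end annotations and
    claims of internal ribosome entry. Selects and orients full-length
    long cDNA reads by template-switching-oligo and polyA structure,
    builds strand-specific single-nucleotide 5'-end coverage tracks from
    spliced alignments, quantifies per-transcript concordance between
    long-read and CAGE transcription start sites (Pearson correlation in
    TSS-centred windows with RPKM filtering), assigns reads to transcript
    models by intron chain, detects smFISH puncta and classifies them as
    nuclear or cytoplasmic against a DAPI mask, and converts polysome
    qPCR cycle thresholds and dual-luciferase plate readings into
    relative abundances. A seed-deterministic synthetic-data generator
    emulates every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
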