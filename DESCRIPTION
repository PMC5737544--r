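Package: utrscreen
Title: CRISPR Tiling-Deletion Screen Analysis of 3'-UTR Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-CRISPR/Cas9 tiling-deletion screens of
    3'-UTRs. Calls Cas9-induced deletions from aligned paired-end amplicon
    reads of genomic-DNA and cDNA libraries, groups them into distinct
    deletion alleles, quantifies each allele's RNA/DNA count ratio, and maps
    per-nucleotide regulatory activity with bootstrap confidence intervals
    and position-wise Mann-Whitney tests. Includes SpCas9 guide enumeration
    and dual-guide excision design for 3'-UTRs, a seeded synthetic-screen
    generator with known ground truth, and ratio statistics for reporter,
    mRNA-decay, 4sU transcription, and enhancer assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicRanges,
    rtracklayer,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    jsonlite,
    optparse
Config/testthat/edition: 3
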