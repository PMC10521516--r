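Package: teloscan
Title: Telomeric Repeat Array Detection and Classification in Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects arrays of canonical (TTTAGGG) and derivative (TTTAAAA,
    (C)CCTGGG-family) telomeric repeats in Oxford Nanopore style long reads,
    classifies them as terminal or interstitial and by monomer-block
    composition, finds ITR-DTR junctions and colocalizations, infers
    consensus monomers (including elongated, higher-order-repeat-like units)
    by wraparound dynamic programming, models derivative monomers as
    recombinants of the G-rich and C-rich telomeric strands, and simulates
    seeded long-read libraries with planted repeat architectures and
    per-base indel/mismatch error models for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
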