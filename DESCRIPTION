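Package: nanobnd
Title: Breakpoint Localization for Balanced Rearrangements from Long-Read
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and localizes breakpoints of balanced chromosomal
    rearrangements (reciprocal translocations and inversions) from long-read
    whole-genome alignments at low coverage. Extracts split-read (chimeric
    alignment) evidence, clusters it into consensus breakend calls with
    confidence intervals, pairs reciprocal junctions and sizes junction
    micro-deletions/duplications, merges independent call sets, estimates
    copy number from windowed read counts in no-control mode, and phases
    reads into haplotypes around breakpoints by minimum error correction.
    Includes a synthetic-data module that generates rearranged diploid
    genomes, nanopore-like reads, and emulated alignments with full truth
    tables, so the whole pipeline is testable without external data or
    aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
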