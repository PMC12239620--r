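Package: tetrack
Title: Tracking Transposable Element Movement Between Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies individual transposable element (TE) copies by the
    single-nucleotide polymorphisms (SNPs) they overlap, projects each
    SNP-fingerprinted copy from a reference assembly into a diverged query
    assembly, and classifies every tracked copy as unmoved, intrachromosomally
    moved, interchromosomally moved, ambiguous, or excluded using
    alignment-expected coordinates from a collinear-block synteny map together
    with a 50-bp flank-similarity filter under asm5-style local alignment
    scoring.  Also provides a workspace-restricted permutation test for the
    enrichment of genomic variant sets in annotation and chromatin interval
    sets (chromosome arm versus center domains), and a synthetic genome-pair
    simulator that plants TE copies, variants, and transposition events with a
    machine-readable truth table for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
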