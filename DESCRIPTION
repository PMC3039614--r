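Package: rrlsv
Title: Structural-Variant Discovery from Paired-End Reduced Representation
    Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects deletions, insertions and inversion breakpoints from
    discordantly mapping read pairs of restriction-digest reduced
    representation libraries (RRLs) sequenced in pools. Covers in-silico
    restriction digestion and size selection with RRL summary statistics,
    read qualification (restriction tag, trimming, per-base quality floor),
    unique best-hit mapping with at most one mismatch (built-in toy mapper or
    SAM ingestion), insert-size based pair classification, single-linkage
    clustering of discordant pairs, an empirical (span-size deviation) x
    support discrimination rule, cross-pool sharing analysis, gene/repeat
    annotation, breakpoint resolution with junction-microhomology detection,
    and a seeded synthetic-data generator that emulates pooled RRL
    sequencing for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    optparse
Config/testthat/edition: 3
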