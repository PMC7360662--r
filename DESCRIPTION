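Package: junctionscan
Title: Targeted Detection of Known Gene-Fusion Junctions in Raw RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds breakpoint-spanning reads for known gene fusions (such as
    KIAA1549:BRAF in pilocytic astrocytoma) directly in raw paired-end RNA-Seq
    FASTQ files, without genome-wide alignment. Builds breakpoint junction
    contigs from a genome FASTA and GTF annotation for a curated whitelist of
    fusions, scans reads by seed-and-verify ungapped matching with explicit
    minimum-overhang and aligned-fraction contracts, aggregates split-read
    evidence to fragment-level support, and calls fusions with a one-read
    rescue rule for whitelisted events. Includes a paired-end read simulator
    with per-fragment ground truth for benchmarking detectability in
    low-fusion-expression regimes, and cohort evaluation in the
    reported/discarded/missed taxonomy with sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
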