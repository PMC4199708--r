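Package: plastomer
Title: Comparative Plastome Structure, Repeats, and Substitution Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of chloroplast genomes
    (plastomes): detection of the quadripartite LSC/IRa/SSC/IRb
    architecture and the extent of genes partially duplicated at the
    inverted-repeat borders; identification of maximal direct and
    palindromic repeats under a Hamming-distance model with the
    consolidation of raw repeat listings into tandem/dispersed classes
    and unique repeat families; and alignment-based SNP counting,
    nucleotide diversity, sliding-window identity, and
    divergence-time-calibrated substitution rates.  Includes a seeded
    synthetic-plastome generator that plants repeats, border genes, and
    sequences evolved along a dated tree, emitting machine-readable
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    data.table,
    ape,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
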