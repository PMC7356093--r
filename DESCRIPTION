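Package: twindiff
Title: Structural Comparison of Near-Identical Bacterial Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares two near-identical bacterial genome assemblies by
    unique k-mer anchoring and chaining, classifies every discrepancy as a
    substitution, one-letter indel or long insert, clusters differential
    long inserts into families by pairwise identity with neighbor-joining
    trees on p-distances and bootstrap support, identifies transposons by
    their terminal inverted repeats and target-site duplications, censuses
    additional element copies genome-wide by exact inverted-repeat match,
    and maps insertions and small variants onto gene annotations to call
    disrupted genes, frameshifts and synonymous changes. A seeded synthetic
    strain-pair generator with machine-readable truth tables makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    withr,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
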