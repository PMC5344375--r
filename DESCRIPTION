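Package: segjoin
Title: Partition-Based Edit-Distance Similarity Join for String Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds all pairs of strings within a given edit distance (a
    similarity self-join or R-x-S join) using a filter-then-verify strategy:
    strings are partitioned into disjoint blocks by collapsed-alphabet
    frequency signatures, candidate pairs are generated through a segment
    inverted index with multi-match-aware substring windows, pruned by
    length, L1 frequency and interval-block filters, and confirmed by banded
    dynamic-programming verification. Provides a blocked parallel join
    schedule that is provably complete and duplicate-free, an equivalent
    staged dataflow engine, seeded synthetic generators with a brute-force
    oracle, plain-text and FASTA readers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
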