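Package: overtrie
Title: All-Pairs Suffix-Prefix Overlap Detection with a Compact Prefix Trie
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds the longest (or all) suffix-prefix overlaps for every
    ordered pair of DNA reads, the core computation of the overlap stage of
    overlap-layout-consensus genome assembly. Reads are indexed in a compact
    prefix trie (radix trie) whose unary chains are stored as lengths and
    resolved against a 2-bit encoded copy of the input text, giving O(n)
    construction and O(k l^2) overlap enumeration for k reads of total
    length n. Includes construction with or without pre-sorting, containment
    prefiltering of duplicate, prefix- and suffix-contained reads, four
    strategies for partitioning the overlap workload across workers,
    synthetic read generators, brute-force reference oracles, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
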