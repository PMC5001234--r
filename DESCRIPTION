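Package: emsfinder
Title: Exact Edit-Distance Motif Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Exact solver for the (l,d) edit-distance motif search (EMS)
    problem: given n sequences, find every l-mer that occurs within edit
    distance at most d of a substring of each sequence. Candidate motifs
    are generated as compact wildcard strings from the exact-distance-d
    neighborhood of every k-mer (l-d <= k <= l+d), with pruning rules that
    make generation nearly duplication free, and are stored either in a
    motif trie with subset-labelled edges or in radix-sorted arrays with
    on-the-fly wildcard expansion. Includes a planted-instance simulator,
    duplication-multiplicity statistics and Monte-Carlo estimation of the
    expected number of spurious motifs in random instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
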