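Package: motiftrie
Title: Sparse-Trie Motif Discovery for ChIP-seq Peak Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: De novo DNA motif discovery for ChIP-seq peak regions using a
    two-phase design: a counting phase built on a sparse k-mer trie with
    exact and bounded-mismatch (Hamming distance <= d) search plus
    background-based enrichment testing, and an optimization phase that
    refines enriched k-mer seeds into position weight matrices with a fast
    expectation-maximization algorithm under OOPS, ZOOPS and ANR occurrence
    models. Includes order-r Markov background estimation, Markov and
    Eulerian (k-let preserving) sequence shuffling, a planted-motif
    synthetic data generator, JASPAR PFM and MEME minimal motif output, and
    a six-metric PWM comparison suite (Euclidean, Manhattan, Hellinger,
    Pearson, Bhattacharyya, Sandelin-Wasserman).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
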