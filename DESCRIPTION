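Package: eqlen
Title: Equivalent Length and Alignment-Free k-mer Fluctuation Statistics for Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free global statistics of DNA sequences built on the
    partition of k-mer types by their A/T-letter count (m-sets). Decomposes the
    squared coefficient of variation of the k-mer frequency distribution into a
    composition-driven non-fluctuating part and a statistical fluctuating part,
    converts the latter into an equivalent length L_e (the length of a random
    sequence with the same fluctuation statistics), and compares equivalent
    lengths against a universal exponential-in-k curve shared by genomes.
    Includes an m-set-normalized similarity index with sliding-window similarity
    matrices, a random segmental duplication (RSD) genome-growth simulator with
    biased point mutations that reproduces the universal curve, and the algebra
    relating simulator parameters to per-site duplication and mutation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
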