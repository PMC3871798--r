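Package: opmalign
Title: Sparse Dynamic Programming Alignment of Fixed RNA Secondary Structures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: General edit-distance alignment of two RNA secondary structures,
    each given as a sequence with one fixed (non-crossing) set of base pairs.
    Implements the quartic-time baseline recursion over base-pair combinations
    and a sparse variant that restricts the recursion to optimal pair matchings
    (OPMs), with an online candidate-pruning rule and a hairpin upper-bound
    gate. Supports base-pair match, mismatch, breaking and removal, affine-gap
    scoring of loop regions, full traceback to a gapped alignment, Vienna
    dot-bracket and bpseq input, Stockholm output, a seeded synthetic structure
    generator, and benchmarking utilities.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    rlang,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
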