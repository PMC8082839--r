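Package: primerscreen
Title: Specificity-Screened qPCR Primer Pair Design from Sequence Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates every candidate primer of a user-chosen length range
    from a multi-sequence DNA database, applies thermodynamic and
    compositional single-primer filters (nearest-neighbor melting
    temperature, GC content, self-complementarity, 3'-end stability),
    removes primers at risk of cross-hybridization with off-target
    sequences using a 3'-anchored suffix index and pigeonhole seed
    partitioning for approximate matching with up to k mismatches, and
    finally filters, scores and ranks all forward/reverse primer pairs per
    target sequence with a Primer3-style penalty. All stages are
    deterministic and invariant to the parallel work partitioning used, and
    a synthetic-database generator with planted off-target sites provides
    ground truth for property-based verification against quadratic
    brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
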