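Package: reptype
Title: Degenerate Primer Design and In Silico PCR for Plasmid Replicon Typing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for PCR-based typing of plasmid replicons from grouped
    reference sequences. Designs degenerate primer pairs over conserved blocks
    of a multiple alignment under explicit constraints (degeneracy cap, perfect
    3' anchor, 5' mismatch budget, amplicon size window), validates them by in
    silico PCR against target and non-target panels, and classifies amplicon
    sequences into replicon subgroups by neighbor-joining phylogeny with
    bootstrap support. Ships the published IncP-9 oriV-rep primer system and a
    seeded synthetic-panel generator with full ground truth so every stage is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
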