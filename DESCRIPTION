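Package: cdr3trackr
Title: Selection and Cross-Donor Tracking of Antigen-Reactive TCR-Beta
    CDR3 Clones and Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying antigen-reactive T-cell receptor beta
    (TCR-beta) CDR3 clones from paired reactive/non-reactive sorted
    repertoires profiled with immunoSEQ-style bulk TCR sequencing, tracing
    them into unenriched naive, central-memory and effector-memory
    repertoires, discovering conserved CDR3 specificity-group motifs
    (local k-mer and global single-mismatch convergence), scoring motif
    enrichment with exact Fisher and two-rate Poisson tests, and calling
    memory-affiliated motifs shared publicly across donors. Includes a
    synthetic repertoire generator with planted reactive clones and motif
    families for end-to-end validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
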