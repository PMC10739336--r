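Package: mdcscan
Title: Molecular Diagnostic Characters from Whole-Plastome Alignments
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identifies species-specific molecular diagnostic characters
    (MDCs, "pure diagnostic sites") in per-genus whole-plastome multiple
    sequence alignments and summarises them for super-barcoding studies.
    Provides inverted-repeat detection and removal for circular plastomes,
    column-state analysis with IUPAC and gap semantics, merging and
    classification of diagnostic columns into substitution/indel/mixed
    variation events, mean pairwise identity and consensus sequences per
    genus, genus-level diversity summaries, Poisson regression and
    Kruskal-Wallis/Dunn comparisons of those summaries, and a synthetic
    alignment generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
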