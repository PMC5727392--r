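Package: branchsense
Title: Sequence Determinants of 3' Splice Site Sensitivity to SF3B1-Targeting Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse why some 3' splice sites respond to
    SF3B1-targeting splicing modulators (Spliceostatin A, Sudemycins) while
    others resist. Scores branch-point candidates by base-pairing potential
    with U2 snRNA and by an SF1 position weight matrix, scores polypyrimidine
    tracts, GC content and intron/exon lengths; quantifies cassette-exon PSI
    and intron-retention PIR from junction read counts and classifies events
    by delta-PSI/PIR thresholds; compares sequence features between regulated
    and non-regulated events with nonparametric statistics, RNA maps,
    cross-drug overlaps and clustering; and simulates splicing event cohorts
    with planted, recoverable drug-response effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
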