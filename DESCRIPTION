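Package: palmpattern
Title: Morphometric Palm Patterns, Quantitative Identification Keys and
    Pairwise Sequence Comparison for Digenean Trematodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative morphometrics of digenean trematodes
    (flukes). Reads specimen-level measurement tables (micrometres),
    summarizes them into min/max/mean species profiles, reconstructs the
    longitudinal extents of internal organs from standard taxonomic
    measurements, and draws deterministic "Palm pattern" plates: schematic
    bar diagrams in which each worm is a black bar with coloured bars
    marking organ positions, rendered either body-normalized (absolute)
    or to scale and midline-aligned (relative). Ships a declarative engine
    for quantitative dichotomous identification keys together with the
    encoded key to grouper-infecting Allopodocotyle species, transcribed
    comparative species profiles, seeded synthetic-specimen and
    aligned-sequence generators, and pairwise nucleotide comparison
    utilities (overlap identity, transition/transversion catalogue,
    Kimura 2-parameter distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
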