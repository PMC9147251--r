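Package: micromod
Title: Micro-Modular Homology Analysis of Genome Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies short ("micro-modular") identity runs shared between
    unrelated genome sequences. Provides affine-gap pairwise alignment (global,
    local, and seeded/banded modes) under a scoring dialect calibrated to a
    randomized-sequence control band, identity-run-length spectra and patch
    encodings of alignments, sliding-frame selection of high-homology segments,
    chunked scans of megabase subjects, composition-matched random genome
    generation, sequence shuffling, and Gumbel (type-I extreme value)
    significance of alignment scores from shuffle nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
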