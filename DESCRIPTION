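Package: retrotrace
Title: Simulation, Calling and Rate Estimation for Endogenous Retrotransposon Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for studying endogenous retrotransposition
    in cell populations from junction-capture sequencing data. Provides a
    synthetic-data generator that plants LINE-1, Alu, SVA and LTR insertions
    carrying the structural hallmarks of target-primed reverse transcription
    (target site duplications, endonuclease motifs, poly-A tails, 5' truncation,
    twin-priming inversions, untemplated nucleotides) into a toy genome and
    emits capture-style junction amplicons; a junction-read insertion caller
    with duplicate collapse, clustering and a two-unique-amplicon reporting
    threshold; a filter cascade labelling calls as de novo in pluripotent
    samples; per-insertion hallmark annotation; library-subsampling sensitivity
    curves with weighted false-negative arithmetic and a sensitivity-corrected
    per-cell retrotransposition-rate estimator; and a permutation test for
    positional bias of insertions within gene bodies.
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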