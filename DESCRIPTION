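Package: fdcalls
Title: Classification and Phylogenetic Reconstruction of Parid FD Call
    Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing the evolutionary history of ordered call
    combinations in tits and chickadees (Paridae) and their relatives.
    Segments annotated note streams into calls, classifies calls into a
    six-way taxonomy (single, repeated, FD, DF, FxD, other combination),
    applies the species-level FD-consistency criterion, fits two-state
    continuous-time Markov (Mk) models of trait evolution on a time-calibrated
    phylogeny by maximum likelihood (equal-rates and all-rates-different,
    compared by AIC/BIC), reconstructs marginal ancestral states by the
    rerooting / up-down algorithms, and quantifies robustness of the
    reconstruction to recording drop-out, species-label flipping, and
    single-recording stringency. Includes seeded generators for Yule trees,
    binary trait histories, and note-level call corpora with realistic
    call-rate and silence-gap structure, so the whole pipeline is testable
    without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
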