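Package: paleoquartet
Title: Quartet-Based Paleogenomic Inference of Phylogeny, Introgression and
    Diversity from Low-Coverage Ancient Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic inference from low-coverage and
    ancient genomes represented as pseudohaploid sequences: a structured
    multispecies-coalescent simulator with an introgression pulse and an
    ancient-DNA damage/coverage observation model, Consensify-style and
    random-read pseudohaploid calling, transversions-only ABBA-BABA D
    statistics with a weighted block jackknife, non-overlapping sliding-window
    neighbor-joining quartet phylogenies with gene- and site-concordance
    summaries, an introgression directionality test based on the distribution
    of roan-sable path lengths in discordant window trees, damage-aware
    pairwise-difference diversity estimation, and mitochondrial alignment
    diversity statistics. All analyses are verifiable against simulation
    truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
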