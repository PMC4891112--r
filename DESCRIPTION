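Package: chromoshatter
Title: Simulation and Detection of Chromothripsis-Like Chromosomal
    Rearrangements from Mate-Pair and SNP-Array Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for studying radiation-induced
    chromothripsis-like genomes at desk scale. Generates synthetic
    reference genomes, plants structural rearrangements (translocations,
    long deletions, fold-back and duplication-type junctions) with
    controlled junction chemistry (microhomology, blunt, templated or
    untemplated insertion), simulates paired-end reads and SNP-probe
    copy-number/BAF tracks, and re-detects the planted events: discordant
    read-pair clustering with support, parental-subtraction, realignment
    E-value and mismatch filters; junction microhomology classification;
    copy-number segmentation and Amp/Del thresholding; and scoring of
    chromosomes against chromothripsis criteria (localized breakpoints,
    oscillating copy states, retained heterozygosity).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
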