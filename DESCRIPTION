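Package: rhythm4c
Title: Rhythmic Chromatin Contacts, Transcriptional Bursting, and Circadian Period Analysis
Version: 0.1.0
Authors@R: person("rhythm4c", "developers", email = "rhythm4c@example.org", role = c("aut", "cre"))
Description: Tools to analyse time-resolved circular chromosome conformation
    capture (4C-seq) contact profiles with locally weighted multilinear
    regression (LWMR), including differential-contact Z-scores and 24-h
    harmonic rhythmicity tests with regularized variance; rhythmicity
    characterization of binned genomic signal tracks with an HSV/Hill phase
    colour encoding; quantification of transcriptional bursting from
    single-molecule RNA FISH image stacks with Gaussian-mixture ploidy
    assignment; and circadian period and phase statistics (chi-square
    periodogram, binomial and bootstrap phase tests). A synthetic-data module
    generates 4C count matrices, FISH nuclei and image stacks, and locomotor
    actograms with known ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
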