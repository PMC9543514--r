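Package: placeremap
Title: Place-Field Remapping Analysis for Open-Field Tetrode Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing place-cell recordings from light/dark/light
    (L1/D/L2) open-field foraging experiments. Builds occupancy and firing
    rate maps from tracked trajectories and spike trains, detects place
    fields and their centres of mass, computes Skaggs spatial information
    and spatial coherence, quantifies remapping between conditions via the
    L1DL2 angle and pairwise centre-of-mass distances, classifies units as
    place or bursting cells from waveform, firing and burst metrics, and
    estimates local field potential band power (delta/theta/gamma) with a
    Welch periodogram and Simpson band integration. Includes a fully seeded
    synthetic-data generator (Ornstein-Uhlenbeck foraging trajectories,
    inhomogeneous-Poisson place cells, bursting units, spectrally shaped
    LFP) so the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
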