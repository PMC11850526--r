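Package: ecogrms
Title: Event-Related Running-RMS Analysis of Mouse ECoG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for event-related electrocorticography
    experiments in which brain activity evoked by periodic light stimulation
    (with or without transcranial diagnostic ultrasound) is summarized by
    running-RMS envelopes of stimulus-locked events. Provides zero-phase
    Butterworth band-pass filtering in second-order sections, RMS-based
    artifact rejection, 10-s event segmentation with 0.25-s running-RMS
    envelopes, per-event scalars over subsets of event length, two-stage
    ratio normalization (second-baseline median, then per-mouse Trial-1
    median), nonparametric statistics (Mann-Whitney U, Kruskal-Wallis) with
    Bonferroni comparison families, BrainVision/BIDS input and output, and a
    synthetic-data generator that emulates the three-cohort, three-trial
    experimental design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
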