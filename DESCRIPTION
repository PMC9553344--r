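Package: eegchansel
Title: EEG Channel Selection for Fatigue Detection via ReliefF-Ordered
    Forward Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects minimal electrode subsets for two-state (rested versus
    fatigued) EEG classification. Extracts per-epoch, per-channel features --
    wavelet-packet subband standard deviations (Theta, Alpha, Beta1, Beta2)
    and fuzzy entropy -- weights channels with a two-class ReliefF update,
    grows channel subsets in descending weight order, and scores each subset
    with stratified cross-validated K-nearest-neighbour accuracy to report
    the smallest subset attaining the best accuracy. Includes EDF and
    delimited-text readers, polyphase resampling, fixed-length epoching, a
    seeded synthetic two-state EEG generator for validation, and a pipeline
    runner with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    yaml,
    jsonlite,
    digest,
    withr,
    optparse,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    class
Config/testthat/edition: 3
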