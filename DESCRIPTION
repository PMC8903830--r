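Package: cofire
Title: Ensemble Co-Activity and Ripple-Spindle Coupling Analysis for
    Longitudinal Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-extraction curation of one-photon calcium-imaging sources
    (footprint shape filters, overlap resolution, calcium-event candidate
    classification, low-activity removal), quantification of synchronous
    ensemble activity as correlated neuron pairs against temporal-shuffle
    nulls, classification of foot-shock-responsive neurons, cross-session
    cell registration with shuffle-normalized Jaccard overlap, linear-SVM
    context decoding with permutation nulls, and dual-site LFP sharp-wave
    ripple and sleep-spindle detection with coupling statistics. Includes a
    synthetic-data generator that produces every input with known ground
    truth so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    e1071,
    signal,
    pracma,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
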