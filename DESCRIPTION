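Package: plvnet
Title: Single-Trial Phase-Locking Networks as Control Signals for Cognitive Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds single-trial functional brain networks from multichannel
    intracranial EEG by computing high-gamma phase-locking values (PLV) in
    sliding time bins, derives weighted-graph statistics (nodal and global
    network strength, communicability) and spectral baseline features
    (high-frequency activity, spectral tilt), and evaluates their ability to
    predict trial-by-trial reaction time with rank-sum and Welch contrasts,
    Pearson correlations, and a permutation-tested support-vector-machine
    decoder. Includes a ground-truthed synthetic session generator with
    controllable per-trial phase coupling, a minimal EDF reader/writer, and an
    end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
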