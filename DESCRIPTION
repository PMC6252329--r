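Package: trialmine
Title: Graph-Based Mining of Representative Single Trials from Evoked
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Selects representative single trials from noisy multi-trial
    evoked EEG/MEG recordings and produces a high signal-to-noise averaged
    waveform with data-driven amplitude and latency estimates. Trials are
    compared by distance correlation, embedded in the plane by classical
    multidimensional scaling, and connected by a Gabriel graph; high-degree
    nodes (hubs) are averaged into the evoked estimate. Includes zero-phase
    FIR/IIR preprocessing, a signal-to-noise-driven filter/degree
    optimizer, hub-scatter variability via weighted global efficiency,
    coefficient-of-variation reliability and band-power summaries, an
    AR-noise trial simulator with ground truth for parameter-recovery
    studies, and PCA/SVD/multiple-linear-regression baseline miners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
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
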