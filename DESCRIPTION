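Package: dynet
Title: Dynamical Networks from Multineuron Spike Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts simultaneously recorded spike trains into weighted
    interaction networks ("dynamical networks") by Gaussian convolution and
    rectified pairwise correlation, quantifies their weighted structure
    (degree, strength, weighted clustering, global efficiency and per-neuron
    fingerprints), compares them against strength- and weight-conserving null
    models, tracks their trial-by-trial evolution, and detects neural
    ensembles as network modules via consensus modularity maximization with
    multi-timescale scanning. Includes a synthetic-recording generator with
    planted coactive ensembles for benchmarking, broom-style tidiers, ggplot2
    autoplot methods, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
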