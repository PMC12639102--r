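Package: ripplefields
Title: Ripple-Independent Hippocampal Replay Detection and Ripple Field
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects hippocampal replay events from Bayesian population
    decoding of place-cell spiking without requiring sharp-wave ripple or
    population-burst triggers, and analyses "ripple fields": spatial maps
    of ripple power (or spike density) over the locations depicted during
    replay, with circular-permutation null models, split-half stability,
    density-based field zones, and directional tuning. Includes a fully
    synthetic session generator (place cells, open-field trajectories,
    replay trajectories, ripple-band LFP transients confined to designated
    zones) so that every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
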