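Package: photoperant
Title: Behavioral and Fiber-Photometry Analysis for Multi-Phase Operant
    Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing operant-conditioning sessions recorded with
    two-channel (405/465 nm) fiber photometry. Parses timestamped behavioral
    event logs from an operant box, segments them into trials under
    classical, operant and cued-operant contingencies, classifies trial
    outcomes and computes latency and count metrics; normalizes calcium
    traces with a rolling-mean delta-F/F, removes shared motion artifacts by
    isosbestic subtraction, detects supra-threshold calcium transients and
    aligns them to behavioral events; converts body-part tracking tables
    into occupancy maps and distance series. Includes a full synthetic
    session simulator (virtual learning mouse, generative two-channel
    photometry, pose trajectories) with ground-truth export for validating
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
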