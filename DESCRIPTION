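Package: gaitmark
Title: Spatiotemporal Gait Analysis from Heel and Toe Marker Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Extracts per-cycle spatiotemporal gait parameters (cycle time,
    swing and stance time, double-support decomposition, step height and
    length, velocity) from motion-capture heel and toe marker trajectories.
    Gait events are located as peaks and valleys of the vertical heel
    position after Hanning-window smoothing, with an alternation rule that
    removes turning-phase detection artifacts. Includes bilateral asymmetry
    indices, condition-level summary and phase-ratio tables, Shapiro-Wilk
    screening with two-sample t-tests for condition comparisons, a seeded
    synthetic gait generator with ground-truth events for validation, and a
    reproducible end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
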