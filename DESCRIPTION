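Package: ca1ensemble
Title: Stimulus-Evoked CA1 Ensemble Dynamics from Simultaneous Calcium
    Imaging and Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous calcium-imaging and local
    field potential recordings of stimulus-evoked hippocampal CA1 ensemble
    activity in acute slices. Detects calcium transients from per-ROI
    dF/F traces by iterative Gaussian baseline fitting with a 4 SD event /
    2 SD boundary rule, measures fEPSP slope and peak from the field
    potential, aligns both modalities on a common 2 kHz timebase, builds a
    thresholded-normalized ensemble trace, segments it into 10 s
    inter-stimulus sweeps, locates the three post-stimulus ensemble epochs
    (first maximum, minimum, second maximum), and quantifies ensemble
    fraction and Hamming-distance pattern similarity against a
    circular-shift shuffle null. Includes a seeded synthetic-session
    generator emulating the recording protocol for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    signal,
    yaml,
    jsonlite,
    e1071,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
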