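Package: stpmotion
Title: Short-Term Plasticity Microcircuits for Motion-Direction
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates small microcircuits of leaky integrate-and-fire
    units coupled by Tsodyks-Markram short-term plasticity synapses and
    driven by binarized moving-bar stimuli, reproducing direction
    selectivity in two competing subpopulations of V1-like units.
    Provides exact event-driven and fixed-step Euler integration of the
    facilitation/depression variables (u, x), a camera-emulating binary
    stimulus pipeline (6 x 1000 frames, frame-to-spike-train encoding,
    direction-dependent release-probability schedules), six-unit and
    two-unit network builders, and response analyses: firing rates with
    onset-skip windows, per-step direction decisions, and pairwise
    spike-count correlations in 1-ms bins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
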