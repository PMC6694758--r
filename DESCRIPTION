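Package: gazepoll
Title: Gaze Polling Analysis for Curve Driving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies gaze polling -- the intermittent cycling of
    a driver's gaze between road-ahead guiding fixations (GF) and eccentric
    look-ahead fixations (LAF) -- in gaze logs recorded while negotiating
    bends. Provides an empirical guiding-fixation reference (per-position
    median with Savitzky-Golay smoothing), a Gaussian-mixture threshold
    separating the GF and LAF areas, piecewise-linear eye-movement
    segmentation, a polling-event state machine with per-bend strategy
    classification, binned eccentricity distributions with Holm-adjusted
    paired comparisons, and 2x3 repeated-measures ANOVAs on polling metrics.
    Includes a synthetic gaze-log generator with ground truth that emulates
    the active/passive x speed study design, so the full pipeline is testable
    without access to raw driving-simulator data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
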