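Package: deseflow
Title: Dynamic Efficient Sensory Encoding for Optic-Flow Heading Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements dynamic efficient sensory encoding: Gaussian
    speed-tuning curves for a finite neural population are continually
    re-derived from the rolling distribution of recently observed optic-flow
    speeds, placing tuning peaks at equal-probability-mass quantiles and
    setting bandwidths inversely proportional to local stimulus density.
    The mechanism is embedded in a two-stage neural model of heading
    perception: an MT-like population with joint direction and speed tuning
    and Gaussian spatial pooling, followed by an MSTd-like bank of radial
    expansion templates with leaky recurrent competition. Includes a
    synthetic ego-motion flow generator (pinhole reprojection through
    parametric depth scenes along seeded multi-segment camera trajectories),
    Middlebury .flo readers and writers, heading-error and logistic-latency
    analyses, and an experiment harness comparing dynamic against static
    tunings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
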