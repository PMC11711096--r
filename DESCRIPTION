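Package: rgcpop
Title: Subunit Receptive-Field Models and Redundancy Analysis for Retinal
    Ganglion Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying redundancy in retinal ganglion-cell population
    responses to natural gaze-shifted stimuli. Provides a ground-truth retinal
    simulator (checkerboard white noise, flashed and flickering sinusoidal
    gratings, natural-like jittered videos, Poisson spike generation from
    linear-nonlinear and subunit-grid encoders arranged in mosaics),
    spike-triggered-average receptive-field characterization, analytic
    difference-of-Gaussians grating responses, maximum-likelihood fitting of
    DoG LN and subunit-grid models (flashed and spatiotemporal variants, with
    density regularization, pruning and BIC model selection), natural-image and
    natural-video response prediction, frequency-domain spike-train information
    rates with fractional redundancy for cell pairs, and decompositions of
    pairwise response correlations by spatial contrast and receptive-field
    nonlinearity, including fixation segmentation of gaze traces and
    direction-selectivity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
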