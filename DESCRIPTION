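Package: lumigain
Title: Rapid Luminance Gain Control in the Fly Visual System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying rapid luminance gain control in early visual
    circuits of the fruit fly. Generates the standard visual stimuli (drifting
    sinusoidal gratings, moving OFF edges, ternary white noise) as luminance
    movies; implements an effective single-compartment membrane/calcium model
    of lamina monopolar cells and fits it to contrast-response data; samples
    contrast-response distributions from synthetic natural scenes along
    stochastic gaze trajectories and scores spatial-pooling extents with a
    Wasserstein-distance loss; simulates a shunting-inhibition divisive
    normalization circuit for transmedullary neurons; and provides the
    calcium-imaging analysis pipeline (dF/F, trial reliability, F1 amplitudes,
    log-luminance slopes, reverse-correlation spatiotemporal receptive fields,
    Gaussian receptive-field fits) together with a synthetic-recording
    generator and connectome point-cloud geometry utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
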