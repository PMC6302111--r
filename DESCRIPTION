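Package: foveate
Title: Active Fovea-Based Visual Scene Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates saccadic exploration of a visual scene with a foveated
    wavelet observation model. Images on a 32x32 grid are encoded as a
    five-level orthonormal Haar pyramid; each gaze orientation reads a
    15-coefficient multiscale visual field centred on the fixation point.
    A Bernoulli-gated Gaussian generative model per (category, viewpoint)
    supports sequential Bayesian evidence accumulation over image
    categories, and a family of predictive action-selection metrics
    (Infomax, Saliency, variational free energy, Compression Improvement,
    and the Information Gain Lower/Upper Bounds) drives saccade selection
    under inhibition of return and an entropy stopping rule. Includes
    pre-processed action maps and saccade trajectories, a deliberately
    corrupted ("faulty") model variant for robustness studies, seeded
    synthetic glyph and toy-world generators for exact oracle testing,
    and an experiment runner comparing recognition accuracy against
    decoding compression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
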