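Package: eiflux
Title: Rainfall Interception Loss from Eddy-Covariance Latent Heat Flux
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers evaporative rainfall-interception loss from flux-tower
    latent-heat measurements with two physics-constrained hybrid models
    trained on wet versus dry hours. Provides a quadratic Penman-Monteith
    forward operator and its closed-form inversion to surface resistance,
    flux-tower quality control and energy-balance corrections, rule-based
    rain-event segmentation with rainfall descriptors, a canopy-water-storage
    latent-variable network, upscaling of the trained models to gridded
    forcing with a sub-grid light-rain correction, rainfall-regime metrics
    and trend attribution, and a synthetic tower generator with a known
    interception ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
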