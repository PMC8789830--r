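Package: octra
Title: Accelerated Optical Coherence Tomography Angiography Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for accelerating optical coherence tomography angiography
    (OCTA) by reconstructing fully-sampled, high-quality enface angiograms
    from undersampled, low-quality ones. Provides a synthetic vascular
    phantom simulator with flow decorrelation across repeated B-scans, an
    angiogram-formation and training-pair pipeline, a two-stage
    convolutional reconstruction network (pixel super-resolution followed
    by quality enhancement, with dense or residual inter-block connections)
    trained with a composite MAE / multiscale-SSIM / Fourier-magnitude loss
    and an optional adversarial stage, interpolation baselines, and an
    evaluation suite including skeleton-based vessel connectivity and an
    acquisition-time speed-up model. Networks run on a small reverse-mode
    automatic-differentiation engine included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    yaml,
    igraph,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
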