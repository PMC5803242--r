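Package: wavetomo
Title: Wavelet Shrinkage Denoising for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Denoising of cryo-electron tomography images and volumes with an
    undecimated, spline-based discrete dyadic wavelet transform (DDWT). Four
    coefficient-modification strategies are provided (direct soft thresholding,
    modified shrinkage with subband-dependent thresholds, spatially adaptive
    neighborhood averaging, and cross-scale regularization); the default
    configuration is a modified wavelet shrinkage filter (three decomposition
    levels, finest level zeroed, subband-dependent soft thresholding). The
    package also ships the evaluation metrics (variance-ratio SNR, MSE, CCC),
    a geometric phantom simulator with SNR-calibrated Gaussian noise, a
    parallel-beam tilt-series projector, and minimal WBP and SIRT
    reconstructors, so denoise-project-reconstruct-evaluate studies run
    end to end without external software. Reads and writes MRC2014 volumes
    and stacks, TIFF images, and plain-text tilt-angle files.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
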