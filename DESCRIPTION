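Package: smlmgan
Title: Simulation and GAN-Based Localization for Single-Molecule
    Localization Microscopy under Lossy Video Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study single-molecule localization microscopy (dSTORM)
    imaged through consumer cameras: a Poisson-Gaussian sensor forward model
    with photon-transfer-curve calibration and dark-series diagnostics, an
    H.264-style 4x4 exact-match integer-transform compression model, a
    blinking-emitter simulator producing paired training data, a classical
    threshold-and-fit localizer, a conditional image-to-image GAN (U-Net
    generator, patch discriminator) that emits single-pixel localization
    maps from degraded frames, and evaluation utilities (ground-truth
    matching, event-density traces, Fourier ring correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    pracma,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
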