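Package: utapr
Title: Universal Adversarial Perturbations for Frozen Image Feature Extractors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for crafting and analysing universal, transferable
    adversarial perturbations against frozen image feature extractors used in
    computational pathology. Implements projected-gradient optimisation of a
    single L-infinity-bounded noise pattern that decorrelates the feature
    embeddings of attacked images from their clean counterparts, together with
    patch-specific and class-specific cross-entropy attacks, a fast
    gradient-sign baseline, a Fourier low-pass-filter defense with effective
    numerical-aperture accounting, an adaptive filter-resilient attack, a
    convolutional attack detector, and a linear-probing evaluation harness.
    Ships a bundled deterministic tiny vision transformer and a synthetic
    generator of H&E-like textured image patches so the full pipeline is
    testable on a laptop without external model weights or datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    knitr,
    rmarkdown
Config/testthat/edition: 3
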