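Package: infantprint
Title: Contactless Infant Fingerprint Simulation, Enhancement and Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-contact infant and newborn fingerprint computation:
    a synthetic finger-image simulator with exact minutiae ground truth that
    emulates infant-specific acquisition physics (fine 125-450 micron ridge
    periods, 4-5:1 ridge-to-valley width ratios, cylindrical foreshortening,
    specular halo saturation, skin peeling, motion blur); the enhancement
    chain (flat-field correction, background smoothing, bimodal contrast
    stretch); ridge-frequency normalization that resamples any finger to a
    fixed 8 pixels-per-ridge template space so newborns and adults become
    directly comparable; crossing-number minutiae extraction and a
    local-descriptor rigid-alignment matcher; and DET/TAR-at-FAR biometric
    evaluation with seeded genuine/impostor campaigns and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
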