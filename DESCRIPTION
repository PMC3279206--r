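Package: srhsi
Title: Sparse-Representation Tumor Detection for Medical Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pixel-level tumor detection in medical hyperspectral reflectance
    cubes by sparse representation over a two-class dictionary of training
    spectra. Provides ENVI-dialect cube input/output, white/dark reflectance
    calibration, per-band median denoising, orthogonal matching pursuit and
    basis pursuit sparse coding, a residual-ratio decision rule with
    morphological hole filling, false-positive/false-negative-rate evaluation,
    and a synthetic tongue-scene simulator so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    png,
    rlang,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
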