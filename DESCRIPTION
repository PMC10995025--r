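Package: bonesr
Title: Super-Resolution and Microstructural Validation for Clinical CT of
    Trabecular Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for enhancing clinical cone-beam CT volumes of trabecular
    bone by single-image super-resolution, together with the validation
    stack needed to trust such enhancement. Training pairs are synthesised
    from high-resolution volumes through a two-stage degradation cascade; a
    residual convolutional network with a factor-four resize-convolution
    upscaler is trained under three composite loss recipes (pixel-wise
    MSE+total-variation, structural 1-SSIM, and a perceptual recipe) with
    patient-grouped cross-validation, and applied to whole volumes through
    Gaussian-weighted sliding windows. Validation utilities cover 3D
    trabecular morphometry (BV/TV, Tb.Th, Tb.Sp, Tb.N via local thickness),
    modulation-transfer-function estimation from line-pair phantoms, and
    agreement statistics (Pearson with Fisher-z intervals, Bland-Altman,
    linearly weighted Cohen's kappa, Wilcoxon signed-rank). Synthetic
    trabecular and quality-assurance phantom generators with known ground
    truth make the whole pipeline exercisable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    RNifti,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
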