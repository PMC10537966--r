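Package: csmrigan
Title: Adversarial Compressed-Sensing MRI Reconstruction with Dilated
    Residual Attention U-Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for compressed-sensing
    MRI. Simulates retrospective k-space undersampling with
    variable-density Gaussian masks and a fully sampled central region,
    generates synthetic brain-like phantoms, and reconstructs zero-filled
    images with a U-net generator built from dilated residual blocks,
    channel attention, and multi-scale information fusion, trained
    adversarially against a strided-convolution discriminator under a
    weighted combination of image-domain, frequency-domain, perceptual,
    and adversarial losses. Includes PSNR/SSIM/MSE evaluation, ablation
    runs, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
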