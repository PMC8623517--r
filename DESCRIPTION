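Package: wavesr
Title: Wavelet-Domain Frequency-Separation Super-Resolution for Grayscale Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-image super-resolution for 8-bit grayscale (chest
    X-ray style) images in the stationary wavelet domain. A one-level
    undecimated Haar transform splits the image into an approximate
    sub-band and three sparse detail sub-bands; two separated lightweight
    convolutional paths -- built from ghost extension blocks and a
    spatial-attention variant -- predict the high-resolution wavelet
    coefficients, which are recombined by the inverse transform. Includes
    the full training loop (Adam, cosine learning-rate decay,
    gradient-norm clipping), closed-form parameter/FLOP accounting for
    the block types, PSNR/SSIM quality metrics, a deterministic
    chest-phantom generator for self-contained experiments, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
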