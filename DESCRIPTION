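Package: spectrastain
Title: Virtual H&E Staining from Visible-Range Spectral Images of Unstained Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational (virtual) Hematoxylin and Eosin staining
    from visible-range spectral image cubes of unstained tissue. Implements a
    Fourier-transform imaging-spectroscopy simulator (interferogram synthesis,
    apodization, zero-filling, phase correction and spectral reconstruction),
    a synthetic tissue phantom that renders registered unstained/stained pairs
    via Beer-Lambert absorption, CIE 1931 colorimetric reduction of spectral
    cubes to RGB, per-pixel principal-component reduction of spectra with the
    associated reconstruction-loss (information) curve, a conditional GAN
    (U-Net generator, patch discriminator) trained with a blurred-L1 plus
    total-variation objective to emit H&E-like RGB images, and paired
    (L1, RMSE, PSNR, SSIM) and distributional (FID, KID) evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
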