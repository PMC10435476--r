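Package: pamgan
Title: Photoacoustic Microscopy B-Scan Enhancement with Paired and Unpaired GANs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts low-resolution acoustic-resolution photoacoustic
    microscopy (AR-PAM) b-scans into optical-resolution-like (OR-PAM)
    b-scans with conditional (paired) and cycle-consistent (unpaired)
    generative adversarial networks. Includes the surrounding pipeline:
    volume I/O and maximum-amplitude projections, A-line bandpass and
    envelope preprocessing, patch extraction and stitching, a dual-PSF
    phantom simulator producing co-registered AR/OR ground-truth volumes,
    ResNet-block generators and Markovian patch discriminators with
    hand-rolled backpropagation, and an image-quality suite (SNR, CNR,
    SSIM, Gaussian-fit FWHM profiling).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    tiff,
    png,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
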