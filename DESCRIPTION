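Package: wedgefill
Title: Missing-Wedge Tomography Reconstruction with a Two-Step
    Sinogram-Inpainting and De-Artifacting GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for limited-angle (missing-wedge) tomographic
    reconstruction of 2-D cross sections, as encountered in electron
    tomography.  Provides a synthetic phantom generator, a parallel-beam
    Radon projector with missing-wedge masking, classical reconstruction
    baselines (weighted back projection, SART, total-variation
    minimization), a two-step joint deep model -- a residual-in-residual
    dense block (RRDB) conditional GAN that inpaints the missing sinogram
    rows followed by a U-net conditional GAN that removes residual streak
    and ghost-tail artifacts from the reconstructed tomogram -- and a
    quantitative/perceptual evaluation suite (PSNR, SSIM, RMSE, NIQE,
    Perceptual Index).  All network layers and training loops are
    implemented in package native code and are fully seeded and
    deterministic on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tiff,
    png,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
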