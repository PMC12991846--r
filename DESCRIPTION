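Package: paiq
Title: Image Quality Assessment for Photoacoustic Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-reference, no-reference and region-based image quality
    assessment for reconstructed photoacoustic images. Implements eleven
    full-reference metrics (PSNR, SSIM, MS-SSIM, IW-SSIM, sparse masked
    SSIM, HaarPSI, FSIM, GMSD, MS-GMSD, pixel-domain VIF, UQI), the
    BRISQUE natural-scene-statistics feature chain, region-of-interest
    detectability metrics (SNR, CNR, gCNR), and a statistical framework
    that ranks metrics by their ability to separate known quality levels
    (significant count, normalized mean difference, composite score).
    Includes a synthetic vessel/Derenzo phantom generator with sparse-view
    and frame-averaging degradation ladders, and lightweight convolutional
    regressors trained to predict full-reference scores from a single
    image, with Grad-CAM interpretability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
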