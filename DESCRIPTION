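Package: ribmnlm
Title: Rotationally Invariant Block Matching Non-Local Means De-Speckling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Speckle reduction for B-mode ultrasound images by non-local means
    filtering restricted to K-means clusters of patches described by Hu moment
    invariants, with rotation- and mirror-compensated block matching (RIBM).
    Includes a Gaussian pre-filter, a conventional non-local means baseline,
    SSIM/PSNR/MSE/RMSE image quality metrics, a synthetic phantom and noise
    generator for self-contained experiments, and an experiment runner that
    sweeps noise levels and cluster counts.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
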