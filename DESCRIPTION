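Package: brightpaint
Title: Label-Free Prediction of Cell Painting Channels from Brightfield Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the five fluorescent Cell Painting channels (DNA, ER,
    RNA, AGP, Mito) from a three-plane brightfield z-stack with a U-Net
    image-to-image model trained under an L1 objective and, optionally,
    continued as the generator of a conditional Wasserstein GAN with
    gradient penalty. Includes tiled inference with median stitching,
    image-level evaluation metrics (MAE, MSE, SSIM, PSNR, PCC),
    morphological profile construction with four-rule feature selection,
    grouped predicted-versus-truth feature correlation, 2-D profile
    embedding, and K-NN toxicity calling with balanced bootstrap majority
    voting. Ships a synthetic paired-microscopy generator so the full
    pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
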