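Package: ctharmony
Title: Harmonization of CT Radiomic Variability at the Image and Feature Level
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for harmonizing CT acquisition- and reconstruction-induced
    variability in radiomic analyses. Implements reference-batch ComBat
    (empirical-Bayes location/scale batch correction) at the feature level, a
    paired WGAN-GP image-to-image harmonizer with a shallow multi-receptive-field
    CNN generator at the image level, and their sequential combination, together
    with a synthetic multi-protocol phantom generator and a complete evaluation
    suite: test-retest reproducibility via Lin's concordance correlation
    coefficient, paired stability testing with Bonferroni correction, tissue
    classification AUC, and image quality metrics (NMSE, PSNR, SSIM). Includes an
    IBSI-aligned extractor for 93 non-shape radiomic features (first-order, GLCM,
    GLRLM, GLSZM, GLDM, NGTDM).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
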