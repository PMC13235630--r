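Package: petsynth
Title: Synthesis and Evaluation of Amyloid PET Images from FDG PET with a
    Conditional GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study cross-tracer brain PET image translation: a
    pix2pix-style 2D conditional generative adversarial network (U-Net
    generator, PatchGAN discriminator, least-squares adversarial loss plus
    L1 reconstruction loss) that synthesizes amyloid-PET-like volumes from
    FDG PET slices, together with the evaluation battery used to judge such
    syntheses: image-quality metrics (MSE, PSNR, slice-wise SSIM),
    Centiloid-style ROI mean quantification, white/gray-matter contrast,
    rank-sum group comparisons, ROI-mean linear regressions, and a
    Gaussian-kernel logistic-regression amyloid-positivity classifier with
    cross-validation and ROC analysis. A paired FDG/amyloid digital phantom
    cohort generator provides fully synthetic, statistically structured data
    so the entire pipeline runs and is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
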