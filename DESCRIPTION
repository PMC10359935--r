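Package: irisinpaint
Title: Two-Stage Residual Attention GAN for Iris Texture Inpainting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-to-fine generative adversarial inpainting of iris
    textures occluded by eyelids and eyelashes.  Provides the coarse repair
    U-Net, the fine repair network built from modified residual blocks with
    dual attention computing connections (squeeze-and-excitation plus
    spatial attention) on its skip paths, and a WGAN-GP critic with a
    smoothed gradient penalty, together with the iris preprocessing
    pipeline (ground-truth segmentation, crop, extent measurement,
    centering pad, resize), seeded synthetic iris/occlusion data
    generation, and evaluation metrics (PSNR, Frechet distance with a
    pluggable embedding, ROC/EER/TAR).  Networks, reverse-mode gradients
    and training are implemented natively on BLAS matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    EBImage,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
LinkingTo: Rcpp
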