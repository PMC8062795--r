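Package: octsharp
Title: Perceptual-Loss Speckle Denoising and Sharpness Evaluation for OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating residual convolutional denoisers
    for optical coherence tomography (OCT) B-scans using deep-feature
    (perceptual) losses in place of pixelwise L1/L2 losses. Includes a layered
    retinal phantom simulator with multiplicative gamma speckle and
    frame-averaged references, a self-contained convolutional network engine
    (DnCNN-style residual denoiser and a tap-able VGG-16 feature extractor),
    a loss algebra combining pixel and per-layer feature terms with optional
    per-channel (LPIPS-style) weights, the patch-based training protocol with
    repeat-and-select model selection and dual-loss monitoring, and a full
    sharpness-evaluation suite: PSNR, per-boundary edge-preserving index (EPI),
    perceptual sharpness index (PSI), just-noticeable blur (JNB), and the
    spectral-and-spatial sharpness measure (S3).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
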