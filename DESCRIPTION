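Package: icgaOtsu
Title: Otsu Threshold Segmentation for Indocyanine-Green Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Histogram-based automatic threshold selection by maximization
    of the between-class variance (the Otsu method), applied to
    indocyanine-green angiography (ICGA) frames from aneurysm surgery.
    Provides the full variance decomposition (within-, between- and total
    variance and the lambda/kappa/eta separability criteria), image
    segmentation with PNG/TIFF input and binary mask output, segmentation
    quality metrics (MSE, global SSIM, shape error, Dice), a seeded
    synthetic angiography phantom generator (bright tubular vessel with a
    saccular aneurysm bulge) for verification without patient data, and
    two-arm clinical outcome statistics (exact percentage rates, Pearson
    chi-square, pooled t-test from summary statistics) together with a
    synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
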