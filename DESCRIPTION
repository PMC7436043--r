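Package: detrusor
Title: Automated Bladder Sac Segmentation and Detrusor Wall Thickness from B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated measurement of anterior bladder (detrusor) wall
    thickness from transabdominal 2D B-mode ultrasound images. Segments the
    bladder sac by polar-coordinate dynamic programming over an inverted
    radial-gradient cost field, tracks the two parallel anterior wall
    boundaries with a multidimensional dynamic program, and converts the
    dual-line separation to a mean wall thickness in millimetres. Includes a
    synthetic sector-phantom generator with known ground truth, a compact
    U-Net-style convolutional segmenter trained with a weighted categorical
    cross-entropy loss, and evaluation tools (Dice, Hausdorff distance, RMSE,
    Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    generics,
    ggplot2,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
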