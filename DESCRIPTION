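Package: iriscal
Title: Iris-Dependent Calibration of Linear Facial Measurements on Frontal
    Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts pixel-space linear measurements on frontal facial
    photographs to millimetres by using the horizontal visible iris diameter
    (HVID) as an in-image ruler: the iris is located and segmented, its
    horizontal diameter is measured in pixels, a constant anatomical value
    (default 12.2 mm) is assigned to it, and the resulting mm-per-pixel
    magnification ratio scales any landmark distance. Ships the full
    evaluation apparatus (detection AP50/AP75/mAP, Dice/IoU/precision/recall
    with a five-fold cross-validation harness, MAE/MSE/RMSE/MAPE and
    Bland-Altman agreement analysis, an assigned-HVID sweep) together with a
    synthetic frontal-scene generator with exhaustively known ground truth,
    so every stage is testable without clinical photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
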