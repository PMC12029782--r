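Package: haloquant
Title: Quantification of Phosphate-Solubilization Halos on Agar Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for measuring the phosphate-solubilization efficiency of
    bacterial colonies from Petri-dish images. Segments colonies (BAC) and
    their solubilization halos (AS) with a classical reference segmenter or
    imports instance-segmentation predictions (YOLO-seg polygon labels, COCO
    JSON), converts polygons to binary masks, calibrates pixels to
    centimeters from the dish diameter, and computes the solubilization
    efficiency Ef = (A + B) / A together with equivalent diameters. Includes
    a seeded synthetic plate generator with exact ground truth, and an
    object-level evaluation protocol (IoU matching, per-class confusion
    counts, precision / recall / F1 / accuracy with two-decimal truncation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
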