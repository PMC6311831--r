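Package: macuseg
Title: Segmentation and Characterization of Skin Macules in Lower-Limb
    Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Three-stage image-processing pipeline for locating and
    characterizing flat discolored skin lesions (macules) in color
    photographs of the lower limbs of patients with diabetes. Stage 1
    segments the skin region by combining a fixed HSV hue band with a
    per-image dynamic YCbCr chroma range that self-tunes to the subject's
    skin tone. Stage 2 enhances luminosity in CIELAB, projects to a
    principal-component grayscale, and thresholds the dark tail of the
    histogram to obtain the candidate lesion region and a percentage of
    damage. Stage 3 labels macule candidates and computes eleven
    features: five morphologic, two intensity, and four Shade Indices
    that express macule color relative to the surrounding healthy skin.
    Includes a four-class feedforward neural-network classifier trained
    by Levenberg-Marquardt, per-feature two-sample t-test group
    comparisons, and a seed-controlled synthetic lower-limb scene
    generator with ground truth for testing without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
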