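Package: fundusscreen
Title: Automated Screening of Diabetic Retinopathy and Maculopathy in
    Colour Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects exudative diabetic maculopathy in colour fundus
    photographs. Implements a fuzzy image preprocessing chain (green
    channel extraction, fuzzy switching median filtering, brightness
    preserving dynamic fuzzy histogram equalisation), localisation of
    the four retinal structures (optic disc by circular Hough
    transform, blood vessels by morphological opening, macula and
    fovea by disc-diameter geometry), global-threshold exudate
    segmentation, on-pixel feature extraction, and a repeated
    random-split evaluation protocol for four standard classifiers.
    Ships a seeded synthetic fundus image generator with full ground
    truth, and descriptive/inferential statistics for multi-expert
    10-stage retinopathy grading tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    e1071,
    class,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
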