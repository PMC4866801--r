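Package: peagrade
Title: Market-Grade and Defect Classification of Field Pea from Multispectral Seed Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for grading field pea (Pisum sativum L.)
    samples from per-seed multispectral image stacks. Each seed is imaged in six
    LED colour channels (405-850 nm) together with a co-registered laser surface
    height map. The package builds segmentation and height-threshold masks,
    extracts thirteen height-corrected colour, size and shape features per seed,
    aggregates seeds to sample medians, and classifies samples into eight
    Australian market grades, or into defective versus non-defective, using
    linear discriminant analysis with nearest-Mahalanobis assignment. A
    synthetic seed-image generator with a calibration/validation design is
    included so that the full pipeline is testable without instrument imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
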