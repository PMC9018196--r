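Package: tendonscope
Title: Ground-Truthed Image Analysis and Multilevel Evaluation for Tendon-Healing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested, reusable pipeline for analysing raster images from
    tendon-healing studies: spatial-domain enhancement, gradient and edge
    operators (Roberts, Sobel, Prewitt), Gaussian-windowed corner response
    with non-maximum suppression, normalized cross-correlation matching of
    corner patches, robust purification of correspondences by RANSAC with a
    truncated squared-residual loss over a per-channel linear colour model,
    and sum-of-squared-differences template localization. A companion
    multilevel fuzzy comprehensive evaluation module derives geometric-mean
    weights from pairwise judgment matrices and ranks candidate anti-adhesion
    biomaterials. A synthetic-scene generator plants ground truth (corner
    coordinates, edge masks, colour transforms, outlier fractions, template
    offsets) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
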