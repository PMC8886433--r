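Package: endostitch
Title: Endoscopic Image Stitching with Scale-Invariant Features and
    Two-Stage Match Purification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Feature-based mosaicking of overlapping endoscope frames.
    Detects difference-of-Gaussians scale-space keypoints, computes
    128-dimensional gradient-orientation descriptors, matches them with a
    KD-tree best-bin-first search, purifies tentative correspondences in
    two stages (bidirectional nearest-neighbour ratio screening followed
    by RANSAC with a chi-squared inlier threshold and a binomial
    image-match verification), estimates the 8-parameter projective
    transform by the direct linear transform, and fuses the registered
    images with gradual-in/gradual-out feathered blending.  A synthetic
    generator of endoscope-like image pairs and planted correspondence
    sets makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    jpeg,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
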