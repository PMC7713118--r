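Package: topimg
Title: Topological Image Modification and Processing for Unsupervised
    Object Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised detection and contrast enhancement of salient
    objects in raster images via 0-dimensional cubical persistent homology.
    Implements topological image modification (box smoothing that destroys
    small-scale topological noise, and border modification that forces every
    border-connected object into the single infinitely-persisting component),
    selection of significant components by the largest gap in the sorted
    lifetime sequence of the persistence diagram, object marking by
    sublevel-set flood fill at the lowest selected death value, and inverse
    distance weighted background interpolation. Includes six generic
    unsupervised segmenters (Chan-Vese type morphological active contours
    without edges, ISODATA thresholding, isocontour polygon fill, k-means
    superpixels, Roberts cross edges, parametric snakes), confusion-matrix
    evaluation metrics, procedural synthetic scene generators with ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
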