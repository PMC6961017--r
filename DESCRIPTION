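Package: gmmconv
Title: Gaussian-Mixture-Filter Graph Convolutional Networks on Superpixel Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Convolutional neural networks on region-adjacency graphs of image
    superpixels, with continuous convolution filters parameterized as Gaussian
    mixture models in a 2-D pseudo-coordinate space. Because the filters live
    in continuous space they can be rotated and mirrored analytically after
    training, which yields rotation-equivariant object detection from a single
    trained network and a bank of its rotated copies. The package provides SLIC
    superpixel segmentation, directed graph construction with hop-distance
    neighborhoods and loops, the GMM convolution layer with exact analytic
    gradients, Adam training with validation-based model selection, oriented
    edge soft-labelling for orientation experiments, a synthetic scene
    generator for profile-view target detection (head plus ear-like structure),
    argmax-node detection against enlarged bounding boxes, and rotation-bank
    decision rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
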