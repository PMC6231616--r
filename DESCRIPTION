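Package: radannot
Title: Radiograph Enhancement and Multi-Axial Image Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Preprocessing, enhancement and automatic annotation of grayscale
    radiographs. Implements contrast-limited adaptive histogram equalization
    (CLAHE), non-local-means denoising, repetition padding to a fixed square
    canvas, and pseudo-RGB layering of the enhanced channels; parses and
    projects mono-hierarchical multi-axial (IRMA-style) annotation codes onto
    five classification schemes; and classifies images with a
    Bag-of-Keypoints representation (dense SIFT, approximate-nearest-neighbour
    k-means codebook, kd-tree quantization, 2x2 spatial histograms, PCA
    reduction) fed to bagged random forests. Includes a synthetic radiograph
    generator so the whole pipeline can be exercised end to end without any
    external dataset, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    optparse,
    png,
    ranger,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
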