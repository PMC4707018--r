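Package: vesselab
Title: Salient-Region Filtering and Segmentation of Immunostained Vessel Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Abstraction and segmentation of blood-vessel regions in
    immunohistochemistry (IHC) images. Implements a salient-region filtering
    algorithm (Gaussian color model, bilateral large-scale/detail layer
    decoupling, soft luminance quantization), a two-stage segmentation
    pipeline (graph-partitioning active contours, Otsu thresholding, a
    spatiochromatic region typing with surrounding-area-ratio and
    area-image-ratio tests, and Niblack-based refinement), a parametric
    generator of synthetic vascular images with exact ground truth, and
    XOR-based count and area error metrics including a fuzzy c-means
    benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    e1071,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
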