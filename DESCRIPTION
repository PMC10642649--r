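Package: mycofrac
Title: Box-Counting Fractal Dimension and Pigment Quantification for
    Mycelial Network Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis of fungal mycelial networks grown
    in microliter drop habitats. Implements the mass fractal dimension of a
    hyphal network by box counting over a geometric series of grid sizes,
    with an edge-preserving Kuwahara smoothing step (classic and linear
    variants), Sobel edge detection, and automatic binarization (isodata,
    Otsu, and Huang fuzzy thresholding). Red pigment secreted into media
    drops is quantified on the CIELAB a* channel with Huang thresholding
    and polygonal drop regions of interest. A synthetic-data module
    generates branching mycelium-like images, analytic fractal fixtures of
    known dimension, and pigmented drop scenes with known ground truth, so
    the whole pipeline is testable without microscope data. Measurement
    tables are compared with two-way ANOVA (Type II sums of squares),
    Tukey honest significant differences, and Welch t tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
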