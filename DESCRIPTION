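Package: islandotsu
Title: Island-Algorithm Metaheuristic Optimization and Adaptive-Bifurcation
    2D Otsu Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A hybrid island-algorithm optimizer enhanced with
    opposition-based learning and a simulated-annealing acceptance rule,
    together with the adaptive-bifurcation two-dimensional Otsu thresholding
    objective it drives. Includes the classical 2D Otsu machinery
    (neighbourhood-mean image, joint histogram, inter-class variance,
    exhaustive oracle), a benchmark-function suite with known optima for
    exercising the optimizer, synthetic phantom images with ground truth for
    testing segmentation without external data, PSNR/MSE quality metrics,
    and a command-line interface for benchmarking and segmenting 8-bit
    grayscale images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
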