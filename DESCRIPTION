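Package: stalkscan
Title: Anatomical Trait Measurement from Flatbed Scans of Grass Stalk Transections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated image analysis of hand-cut grass stalk transections
    imaged on a flatbed scanner. Segments stalk sections from a dark background
    by Otsu thresholding, filters debris by size and eccentricity, and measures
    whole-section morphometry (area, mean diameter, perimeter). Locates the
    pith/rind boundary by Gaussian filtering of the green channel and reports
    mean rind thickness via Euclidean distances between the outer and pith
    boundaries. Detects vascular bundles in the pith with bundle-scale Gaussian
    smoothing, Perona-Malik anisotropic diffusion and non-maximum suppression,
    and reports bundle count and density. Measures individual bundle size by
    homomorphic illumination correction of a 40x40 patch followed by a
    full-covariance 2D Gaussian fit. Includes a seed-deterministic synthetic
    transection generator with exact ground truth, a batch pipeline writing
    trait tables and provenance sidecars, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    tiff,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
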