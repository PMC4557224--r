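Package: histofield
Title: Scalar-Field Representation of Objects in Histological Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents discrete objects in histological images (cell nuclei,
    bone trabeculae) as continuous scalar density fields by convolving object
    centroids or masks with an inverse multiquadric radial basis function.
    On these fields the package computes colocalization and spatial
    interaction statistics (Pearson correlation, Manders overlap and split
    coefficients) between registered serial sections, histogram-intersection
    distance surrogates for niche allocation, and gradient/divergence sink
    detection for cluster description. Includes a synthetic image generator
    (binary test patterns and pseudo-immunohistochemistry images with ground
    truth), a brightfield preprocessing chain (colour deconvolution, nucleus
    segmentation, watershed separation, stained/non-stained classification),
    and plain TIFF/PNM/CSV/JSON readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
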