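Package: hyperrow
Title: Segmentation and Per-Plant Trait Extraction for Push-Broom
    Hyperspectral Images of Row Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated processing of lateral-view push-broom hyperspectral
    images of row-grown bush crops (developed around field images of
    raspberry rows). Detects plant material in VNIR images with an NDVI
    threshold, morphological erosion and a graph-based minimum-cost seam
    that removes the grass strip below the cardboard background, and in
    SWIR images with a water-absorption normalised-difference index and
    Otsu thresholding. Locates the in-frame white reflectance standard in
    both scanners, filters occluded columns, and converts digital numbers
    to reflectance with a sectioned white-reference normalisation. Splits
    each row image into individual plants from the column-wise plant-pixel
    profile and extracts per-plant height, density and mean reflectance
    spectrum. Includes a seeded synthetic-scene simulator with full ground
    truth so the whole pipeline can be exercised without field data, plus
    ENVI-style cube input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
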