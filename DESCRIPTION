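Package: fptag
Title: Cell Identification from Trichromatic Split Fluorescent Protein
    Intensity Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying cell populations labeled with tandem
    arrays of split fluorescent protein (FP11) tags whose copy numbers
    encode a trichromatic intensity barcode. Provides tag-library
    combinatorics, a calibrated synthetic-data generator for per-cell
    intensities and labeled spatial point patterns, background correction
    and spherical-angle featurization, a class-conditional Gaussian
    mixture classifier with posterior membership probabilities, pairwise
    discriminability matrices with max-min panel selection, and spatial
    interaction statistics (Clark-Evans index, permutation-null
    nearest-neighbor adjacency ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
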