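Package: orchardcrowns
Title: Tree Crown Delineation and Size Classification in Semi-Overlapping Orchards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates and size-classifies tree crowns in semi-overlapping
    orchards from high-resolution multispectral rasters. Implements a
    five-stage pipeline: unsupervised canopy masking by k-means clustering of
    pixel spectra (with an Otsu thresholding baseline), planting-grid tree
    localization from three anchor trunk positions and surveyed row spacings,
    overlapping crown-sampling boxes of the maximum crown diameter, three-class
    canopy size classification from per-box pixel counts, and classified-map
    plus tabular reporting. Includes pixel-level precision/F1 scoring against
    labeled masks and a synthetic-orchard scene generator with full ground
    truth, so every stage is testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
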