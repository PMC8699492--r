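Package: semquant
Title: Quantitative Cell Morphometry for Scanning Electron Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric analysis of calibrated scanning electron microscopy
    (SEM) images of cells. Provides segmentation of grayscale micrographs into
    binary masks and labeled cell instances; rod-shaped bacterial metrics
    (length, width, aspect ratio, projected area, spherocylinder volume and
    surface, surface-to-volume ratio); neuronal descriptors (soma size, neurite
    count and lengths, radial distance and straightness, angular alignment
    classes, area, perimeter, circularity, differentiated-cell counting);
    box-counting fractal dimension and gliding-box lacunarity of binary
    silhouettes; gray-level co-occurrence matrix (GLCM) texture descriptors
    (angular second moment, entropy, contrast, correlation, inverse difference
    moment); and seeded synthetic-image generators with exact ground truth for
    validation. Includes a command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
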