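Package: stomamap
Title: Large-Area Stomatal Density Mapping from Chlorophyll
    Autofluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects stomata in chlorophyll-autofluorescence leaf
    micrographs and quantifies their spatial patterning over large areas.
    Images are preprocessed by contrast-limited adaptive histogram
    equalization (CLAHE) and median filtering, stomata are located by
    multi-method automatic thresholding (Moments, Li, Minimum) with
    particle-level area and circularity gates, and non-stomatal regions
    (veins, leaf borders) are removed by Percentile-threshold exclusion
    masking.  Stomatal density is mapped on a 1 mm^2 grid and its spatial
    heterogeneity summarised by relative global deviation, the coefficient
    of variation, and global and local Moran's I over k-nearest-neighbour
    weights.  A Monte Carlo subsampling module determines the minimum leaf
    area needed for reliable density estimates, and a seeded synthetic
    leaf-image generator with known ground truth supports end-to-end
    validation of the detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    grDevices,
    graphics,
    utils,
    tools
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
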