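Package: faprox
Title: Quantification of Post-Golgi Secretion Hotspots at Focal Adhesions
Version: 0.1.0
Authors@R: person("faprox", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Image-quantification toolkit for fluorescence microscopy of
    post-Golgi secretion near focal adhesions (FAs). Provides segmentation
    of FA and cargo channels (Gaussian filtering plus thresholding),
    Find-Maxima-style spot detection and counting, an exact distance-to-FA
    enrichment-ratio statistic with a whole-cell baseline, vesicle tracking
    with velocity and track-length metrics, kymographs and temporal
    projections, object-based and Pearson colocalization, a secreted-fraction
    ratio for pulse-chase blot data, and a seeded synthetic-microscopy
    generator with ground truth so every stage is testable without real
    data. Includes a command-line pipeline with stable CSV/TIFF/JSON file
    contracts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
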