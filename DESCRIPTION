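Package: cgExoTrack
Title: Single-Granule Tracking and Cortical Actin Clearance Analysis for
    TIRF Imaging of Exocytosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse total internal reflection
    fluorescence (TIRF) imaging of cortical granule exocytosis in mouse
    eggs. Provides difference-of-Gaussians spot detection with sub-pixel
    localization, two-phase linear-assignment particle linking with gap
    closing, a track library computing per-timepoint and per-track
    features (percent-of-max intensity regression, duration classes,
    appearing/vanishing/stationary classification, minimum enclosing
    ellipses), quantification of cortical actin clearances (percentile
    thresholding, connected-component area/circularity filtering,
    frequency per square micron), granule-actin contact and
    cortex-versus-cytoplasm intensity measures, plus a ground-truthed
    synthetic TIRF movie and actin-cortex image generator for validating
    every stage. Reads TrackMate XML and multi-page TIFF; writes CSV
    tables, JSON manifests and diagnostic figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    xml2,
    yaml,
    jsonlite,
    clue,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    hexbin
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
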