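Package: phagoquant
Title: Quantification of Large-Particle Internalization and RAC1 FRET
    Biosensor Imaging in B Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipelines for B-cell large-particle phagocytosis.
    Implements an imaging-flow-cytometry internalization score that separates
    membrane-bound from internalized particles on single-cell event images
    (cell/particle segmentation, focus gating, radius-corrected centroid
    distance, cohort gating statistics, time-course AUC), and a ratiometric
    FRET biosensor pipeline for localized RAC1 activation during engulfment
    (background correction, stack alignment, smoothing, donor bleed-through
    correction, Venus/Cerulean3 ratio maps, membrane-versus-cytosol activation
    traces).  A synthetic-data module generates ground-truthed event images
    and biosensor stacks so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
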