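Package: micromorph
Title: Microglia Morphometry and Shape-Mode Analysis for Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies microglial morphology in 2D fluorescence micrographs of
    Iba-1-stained brain tissue. Provides a seven-method automatic threshold survey
    with minimum-cross-entropy (Li) segmentation, physically derived small-object
    filtering, per-cell geometric features (area, perimeter, circularity, aspect
    ratio), quadrant splitting with edge-cell removal, population shape-mode
    analysis by registered-contour principal components and k-means clustering,
    nonparametric group statistics (Kruskal-Wallis with Dunn's post hoc test),
    scalar assay helpers (PI cytotoxicity, extracellular-vesicle purity, dot-blot
    signal-density ratios, delta-delta-Cq fold change), and a synthetic
    fluorescence image generator with per-cell ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
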