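Package: interheat
Title: Interactive Cluster Heatmaps as Standalone HTML Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds publication-ready cluster heatmaps and exports them as
    fully self-contained interactive HTML files (hover tooltips, zoom, pan)
    plus static PNG images. Provides per-column matrix transforms (square
    root, z-score, min-max normalization, ECDF percentize, missingness
    indicator), hierarchical clustering of rows and columns with
    silhouette-based automatic selection of the number of clusters,
    optimal-leaf-order seriation of dendrograms, perceptually ordered
    sequential and divergent color scales, categorical annotation sidebars,
    and a command-line front end. Synthetic-data generators with planted
    cluster structure and surveillance-style count matrices support testing
    and demonstration without external data.
License: GPL-2
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    cluster,
    vegan,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
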