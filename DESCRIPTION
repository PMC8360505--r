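Package: wormplate
Title: Post-Processing, Quality Control and Visualization of High-Throughput
    C. elegans Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to read, resolve, filter, summarize and visualize
    per-object measurement tables exported by CellProfiler's WormToolbox for
    96-well C. elegans assays. Resolves the one-to-many relationship between
    animals and worm-model objects by frequency-ranked model selection, flags
    clustered objects, objects near the well edge, and within-well outliers
    (Tukey's fences), prunes flagged data, and summarizes animal length per
    experimental unit. Includes plate/well/dose visualizations and a synthetic
    plate generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    patchwork,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
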