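Package: cortexmech
Title: Actin Cortex Mechanics and Morphology from AFM Confinement and
    Confocal Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-cell actin-cortex mechanics and
    morphology. Converts parallel-plate AFM confinement recordings into
    cortical tension, cortical stiffness and phase shift through a
    constant-volume minimal-surface cell-shape model; quantifies
    cortex-associated fluorescence (cortex-to-cytoplasm ratio) and cortical
    thickness from equatorial confocal images via a skewed-Gaussian radial
    profile model; computes roundness and largest cross-sectional area of
    mitotic cells and spheroids; and provides seeded synthetic-data
    generators for every input so each stage is validated by parameter
    recovery. Group comparisons use exact Mann-Whitney U tests with boxplot
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
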