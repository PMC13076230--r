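Package: pillarwrap
Title: Quantification of Oligodendrocyte Myelin Wrapping on Hydrogel
    Micropillar Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for in vitro myelination assays on
    polyacrylamide micropillar arrays. Detects pillar grids in confocal
    z-stacks, calibrates hydrogel swelling against mold dimensions,
    measures angular myelin (MBP) coverage around each pillar and assigns
    an ordinal 0-3 wrapping score, estimates myelin ring thickness and the
    g-ratio g = D/(D + 2t), counts nuclei to derive per-cell wrapping
    statistics, extracts Young's moduli from AFM force-distance curves via
    a spherical Hertz contact fit, and quantifies lamellar myelin
    ultrastructure (layer counts, band thickness, thickness-versus-layers
    regression) from TEM transect profiles. Ships a seeded synthetic-data
    generator emulating pillar-field image stacks, Hertzian force curves
    and lamellar intensity profiles with ground truth, so the whole chain
    is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
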