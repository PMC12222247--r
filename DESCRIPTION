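Package: grainspectra
Title: Multispectral Autofluorescence Analysis of Developing Wheat Grain Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for series of macroscopic multispectral
    autofluorescence images of wheat grain cross-sections across
    developmental stages. Assembles 11-channel fluorescence cubes from four
    RGB filter acquisitions, corrects per-channel backgrounds, segments the
    whole-section and outer-tissue regions of interest, fits a single
    principal component analysis over all section pixels of the series by
    streaming accumulation of cross-product statistics ("large PCA"),
    quantifies per-image score distributions on shared percentile bins, and
    compares developmental stages on similarity maps. Includes a
    ground-truthed synthetic phantom generator emulating the tissue
    geometry, fluorophore pseudo-spectra and stage trajectories of the
    study design, used by the tests and the reproduction scripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
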