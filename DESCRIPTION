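Package: sulcmap
Title: Sulcal Anatomy and Retinotopic Cortical Magnification in V1
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how occipital sulci (the retrocalcarine and external
    calcarine sulci) relate to the retinotopic map of primary visual cortex.
    Provides readers for cortical surface geometry and per-vertex overlays
    (FreeSurfer binary, GIFTI, CSV), surface areas and edge-graph geodesic
    distances on triangle meshes, phase-encoded traveling-wave analysis of
    retinotopic time series, polar-angle based V1 delineation with a foveal
    confluence line, exponential cortical-magnification curve fitting
    E = a(exp(b*d) - 1), per-sulcus morphometric and visual-field summaries,
    species-by-hemisphere ANOVA, and a synthetic folded-V1 generator with
    human and macaque presets used for validation and as a stand-in for
    restricted neuroimaging datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    minpack.lm,
    jsonlite,
    xml2,
    car,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
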