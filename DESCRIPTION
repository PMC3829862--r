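Package: fretscreen
Title: Simulation and Analysis of Single-Cell FRET Calcium Imaging Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-content screening assays that read out agonist-evoked
    endoplasmic-reticulum calcium release with a ratiometric FRET sensor in
    384-well time-lapse imaging. Provides a ground-truthed synthetic plate
    generator (cell fields, calcium transients, optical rendering, plate
    layouts), nuclear and cell-boundary segmentation with edge-cell exclusion,
    per-cell ratio and dF/F0 trace extraction with responsiveness calls,
    plate-level DMSO normalization, hit calling, autofluorescence/toxicity
    artifact filtering and Z-prime quality control, four-parameter log-logistic
    dose-response fitting (EC50/IC50), and OptiSim-based compound clustering
    with activity annotation for structure-activity analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
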