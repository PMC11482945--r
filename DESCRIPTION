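Package: nanotag
Title: Quantification of Nanogold Labeling in Electron Microscopy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying gold-nanoparticle labeling of tagged
    macromolecules in electron microscopy volumes. Simulates ground-truthed
    gold-labeled scenes with a tethered-label geometry, reads and writes MRC
    volumes and particle coordinate tables (CSV and a minimal STAR dialect),
    detects and sizes high-contrast gold particles by thresholded connected
    components, damps gold signal so it does not dominate subtomogram
    alignment, computes nearest-distance labeling efficiency with a
    structural-offset correction, separates multiplexed gold sizes with a
    two-component Gaussian mixture, and estimates per-cell protein copy
    numbers from imaged-volume extrapolation, fluorescence standard curves
    and flow-cytometry reference ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
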