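Package: plaquematch
Title: Histology-Referenced Validation of Intravascular Plaque Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Warps annotated histology cross-sections of atherosclerotic
    vessels onto the pressurized lumen geometry of matched intravascular
    imaging frames (NIRS-IVUS or OCT) and quantifies agreement between
    histological and machine-estimated plaque composition. Provides lumen
    contour arc-length parameterization, landmark-driven circumferential
    mapping with physical-depth-preserving radial transfer, per-frame plaque
    size quantities (EEM area, plaque area, plaque burden), a paired
    statistical battery (Bland-Altman, Lin's concordance correlation,
    Mann-Whitney U, Kolmogorov-Smirnov-gated t-test, Pearson correlation),
    region- and area-level confusion matrices for fibrotic, calcific and
    necrotic-core tissue with missed-tissue accounting, CD68-based
    macrophage-rich region detection, and a seeded synthetic matched-pair
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
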