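Package: patternscope
Title: Multiscale Structural Complexity and Boltzmann Entropy of Spatial Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multiscale structural complexity and configurational
    (Boltzmann) entropies of 2D raster patterns and 3D voxel fields, together
    with a lossy-compression complexity index (ICRMSE). Includes seeded
    simulators of two-fluid lattice mixing and the 2D Ising model, observation
    transforms (lateral projection, cross-section, resolution coarsening, band
    strategies), and series analysis tools (derivatives, phase-transition
    detection, trend classification, correlation) for studying how the
    dimension and resolution of an observation shape the apparent complexity
    of a dynamic system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jpeg,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jsonlite,
    optparse
Config/testthat/edition: 3
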