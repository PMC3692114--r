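Package: volnma
Title: Normal Mode Analysis of Electron Microscopy Density Volumes via
    Gaussian Pseudo-Atoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts three-dimensional electron microscopy density volumes
    into coarse-grain models of weighted isotropic Gaussian pseudo-atoms at a
    target approximation error, computes elastic-network normal modes of the
    pseudo-atomic structure, scores the collectivity of each mode, measures
    overlap between modes and observed conformational changes, and exports
    deformed structures and animation trajectories. Includes readers and
    writers for MRC2014 and SPIDER volume formats, a pseudo-atom PDB dialect,
    a synthetic two-domain phantom generator for end-to-end validation, and a
    command-line pipeline (mask, convert, nma, animate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
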