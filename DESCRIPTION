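Package: softcut
Title: Cuttable Meshless Soft-Body Simulation with Fixed-Width Connectivity Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implicit-dynamics simulation of cuttable soft bodies discretized
    with the Element-Free Galerkin method: moving-least-squares shape
    functions over a node cloud, cubic integration elements, lumped mass,
    and a matrix-free conjugate-gradient solve of the backward-Euler system.
    The central data structure is a fixed-row-width table store for the
    element-node connectivity graph, shape-function values and gradients,
    and the surface-vertex embedding, with batch-granular dirty tracking and
    a transfer ledger that quantifies what a host-to-device mirror would
    copy per frame, so that localized cuts update only a small fraction of
    mirrored memory. Includes a synthetic torus test scene, a swept-blade
    cutter with coplanarity-checked neighbor re-selection, plain-text model
    and OBJ file formats, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
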