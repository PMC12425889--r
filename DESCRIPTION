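Package: hbmpose
Title: Hard-Constrained Laplacian Positioning of Finite-Element Body Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-free repositioning of volumetric finite-element
    meshes, aimed at human body models (HBMs) used in injury biomechanics.
    Posed skin and skeleton surfaces act as hard positional constraints on a
    weighted graph Laplacian built from element connectivity; interior free
    nodes are recovered by preserving differential coordinates through a
    sparse constrained linear solve. Thin-plate-spline interpolation
    predicts targets for extra constrained nodes near joints before the
    solve, and repairs distorted elements afterwards. Includes an LS-DYNA
    keyword reader/writer, boundary-surface extraction, scaled-Jacobian and
    aspect-ratio quality metrics, a surface penetration checker, and a
    seeded generator of articulated two-segment limb fixtures so the full
    pipeline is testable without licensed body models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
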