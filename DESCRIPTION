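Package: morphograft
Title: Morphoelastic Simulation of Skin Graft Contraction and Contracture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuum mechano-chemical simulation of the contraction and
    contracture formation of skin grafts placed over excised burns. The dermal
    layer is modelled as an isotropic, heterogeneous, morphoelastic solid
    coupled to reaction-transport kinetics of fibroblasts, myofibroblasts, a
    generic signalling molecule and collagen. The package provides the
    dimensional parameter set with an equilibrium-consistency solver, graft
    geometry and initial-field builders, a positivity-preserving moving-grid
    (Lagrangian) P1 finite-element engine with flux-corrected transport,
    source-term splitting, adaptive time stepping and longest-edge mesh
    refinement, a scenario driver that tracks the relative surface area of the
    graft through a tracer polygon, and an independent stiff-ODE oracle of the
    spatially homogeneous reduction for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    methods,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
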