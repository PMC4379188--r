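Package: taxisim
Title: Single-Cell Migration and Morphology in 3D Multi-Cue Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete finite-element simulator of a single cell migrating
    inside a 3D elastic substrate under combined mechanotactic (durotaxis),
    thermotactic, chemotactic and electrotactic (dcEF) guidance. The cell is
    a face-connected set of hexahedral elements that probes its
    micro-environment by a mechano-sensing contraction, converts sensed
    strains into an active+passive contractile stress and nodal traction
    forces, balances traction, protrusion, electric and drag forces, and
    migrates by discrete extension/retraction remodeling of its element set.
    Reports trajectory and morphology metrics: Cell Morphological Index,
    elongation, Random Index and the equilibrium plane of the centroid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
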