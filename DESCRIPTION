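Package: retarrays
Title: Particle Arrays, Hinge Geometry, Conservation Surfaces and
    Tight-Binding Affinity for RET Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for structural studies of the RET receptor
    tyrosine kinase and its GDNF-family ligand/co-receptor complexes.
    Detects linear particle arrays in cryo-EM 2D-classification metadata
    (RELION-dialect STAR files): neighbour-pair detection within a centroid
    cutoff, symmetry-folded in-plane angle differences, binned
    distance/delta-psi distributions and peak statistics.  Includes a
    synthetic micrograph-coordinate simulator with planted arrays and known
    ground truth, rigid-body superposition and hinge-angle measurements on
    atomic models, a residue-class conservation score mapped into B-factors
    for surface rendering, and dissociation-constant fitting with the
    receptor-depletion (tight-binding) quadratic model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
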