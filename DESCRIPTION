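Package: chainscales
Title: Geometry Statistics and Monte Carlo for Tangent-Sphere Chains and
    Protein Backbones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the conformational geometry of a
    coarse-grained polymer with protein backbone geometry.  Implements a
    replica-exchange Monte Carlo simulator for the tangent-hard-sphere
    chain with square-well attraction (WHAM specific heat, infinite
    temperature sampling), geometric kernels for chains of points
    (bond-bending and dihedral angles, three-body circumradii, four-body
    circumsphere radii, nearest non-local contact maps, characteristic
    local and non-local length scales), closed-form inverse-radius
    distributions for fixed-bond random walks, synthetic generators for
    random walks, uniform ball points and ideal alpha-helix / beta-sheet
    C-alpha traces, and ingestion of real protein chains from PDB and
    DSSP files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
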