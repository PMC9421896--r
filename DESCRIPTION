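Package: ssmech
Title: Steered Coarse-Grained Dynamics of Proteins with Breakable Disulfide Bonds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale coarse-grained steered molecular dynamics toolkit for
    studying how the redox environment controls the mechanical stability of
    disulfide-bonded proteins. Provides a structure-based (Go-type) background
    potential with two interaction centers per residue, a redox-tunable
    double-well disulfide potential in which bonds can break and re-form
    between any cysteine pair, a triplet repulsion preventing trivalent
    disulfides, a flat-bottom breaking restraint with a constant-force linear
    tail, a BAOAB Langevin integrator with constant-velocity pulling, and the
    matching analysis pipeline: force-extension profiles in 1 Angstrom bins
    with standard errors, disulfide bond-fraction and native-contact tracking,
    peak detection, Kabsch-superposition RMSD, representative-conformer
    selection, and bond-breaking order statistics. Synthetic crosslinked toy
    folds (including a ribonuclease-A-like mimic with four native disulfides)
    are generated internally; real single-chain structures can be loaded from
    PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    igraph,
    yaml,
    bio3d
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
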