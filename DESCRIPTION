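Package: cyclohelix
Title: Supramolecular Chirality, Interactions and Mechanics of Peptide
    Micro-Rope Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural analysis of self-assembled cyclo-dipeptide crystals
    that pack into supramolecular triple-helical "micro-ropes". Reads
    small-molecule CIF/PDB/XYZ structures and coordinate trajectories,
    performs periodic-boundary geometry (symmetry expansion, supercells,
    minimum-image distances, stacking-layer assignment), detects hydrogen
    bonds, heavy-atom contacts and pi-pi stacking with standard geometric
    criteria, computes the hydrogen-bond rotation-angle profile along the
    helix axis and classifies the supramolecular twist as S (left-handed)
    or Z (right-handed), fits helices (pitch, radius, handedness), builds
    free-energy landscapes from binned observables, and extracts mechanical
    metrics from tensile stress-strain and AFM nanoindentation force curves
    (Hertz contact model). Ships a seeded synthetic generator of
    ground-truth-labelled triple-helix structures, trajectories and force
    curves so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
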