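Package: backrubr
Title: Backrub Backbone Motions in Protein Motifs: Detection, Ensembles,
    and Rotamer-Based Design
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the backrub, a local protein backbone
    motion in which a dipeptide rotates about its flanking Calpha-Calpha
    axis with small counter-rotations of the two peptides.  The package
    reads and writes PDB coordinate files, applies and fits backrub moves,
    mines coordinate sets for alpha-helix N-cap and antiparallel
    beta-sheet aromatic motifs with DSSP-style hydrogen-bond criteria,
    superposes and averages motif ensembles, and performs an exhaustive
    backrub-aware rotamer design search scored with molecular-mechanics
    electrostatics and van der Waals terms plus EEF1 implicit solvation,
    returning the provable global minimum energy conformation over the
    enumerated space.  Synthetic-data generators provide ideal helices,
    antiparallel sheets, and noisy two-population motif ensembles with
    recorded ground truth for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'geometry.R'
    'build.R'
    'structure-io.R'
    'torsions.R'
    'hydrogens.R'
    'hbonds.R'
    'backrub.R'
    'motifs.R'
    'ensemble.R'
    'energy-params.R'
    'energy.R'
    'rotamers.R'
    'design.R'
    'synthetic.R'
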