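Package: insulinconf
Title: Conformational Classification and Bridge Geometry of Insulin Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies insulin monomers from PDB/mmCIF coordinate files into
    T/R states and into the two A-chain N-terminal helix conformations
    (Class 1, alpha-helical i,i+4 hydrogen bonding of the Thr-A8 amide to
    Glu-A4; Class 2, pi-like i,i+5 bonding to Val-A3) using Kabsch-Sander
    backbone hydrogen-bond energies. Extracts the geometry of the three
    insulin bridges (A6-A11, A7-B7, A20-B19): Calpha-Calpha distances,
    disulfide chi dihedral conformers and dicarba cis/trans isomerism.
    Fits A-chain helix axes and per-residue azimuthal positions, and
    summarises multi-model conformational ensembles (per-frame RMSD against
    a Class 2 reference, Thr-A8 hydrogen-bond partner occupancies, class
    occupancy and helicity). Includes a synthetic-structure generator that
    builds two-chain insulin-like monomers and ensembles from backbone
    torsions so that every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
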