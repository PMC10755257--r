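Package: hemeNSD
Title: Normal-Coordinate Structural Decomposition and Structural
    Descriptors for Heme Porphyrins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the distortion of heme porphyrin rings in
    macromolecular structures by normal-coordinate structural
    decomposition (NSD): an idealized planar D4h Fe-porphine reference is
    built, the twelve canonical low-frequency normal modes (saddling,
    ruffling, doming, waving, propellering, meso-stretching, N-pyrrole
    stretching, translation, breathing, rotation) are obtained from a
    harmonic valence force field by solving the mass-weighted secular
    equation, and each observed heme skeleton is rigidly superposed on
    the reference and projected onto the mode basis. Also extracts hemes
    from mmCIF files with model/altloc selection rules, annotates axial
    ligands by a 3.1 Angstrom iron-distance rule, and computes
    out-of-plane iron displacement, propionate dihedral orientations,
    solvent-accessible-surface coverage, bond geometry statistics, and
    group-level feature analyses (histograms, PCA on fitted coordinates,
    LDA on NSD amplitudes, and four clustering methods).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    kernlab
Suggests:
    withr,
    testthat (>= 3.0.0),
    bio3d,
    MASS,
    jsonlite
Config/testthat/edition: 3
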