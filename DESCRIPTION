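Package: helixnmr
Title: Chemical-Shift-Tensor Analysis and Oriented-Sample NMR Simulation
    for Helical Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of first-principles NMR shielding calculations
    for helical membrane peptides such as the peptaibol alamethicin.
    Converts computed chemical-shielding tensors to theoretical chemical
    shifts via linear calibration, determines the orientation of 15N amide
    and 13C carbonyl shift tensors relative to their peptide planes,
    parametrizes the helix (axis, per-residue azimuthal rotation rho, tilt
    tau versus the membrane normal), characterizes the backbone
    (Ramachandran angles, hydrogen-bond inventory), and simulates
    orientation-dependent solid-state NMR observables for peptides in
    aligned lipid bilayers, including the tilt dependence of the parallel
    15N shift component and the azimuthal oscillation of the total 13C
    chemical-shift anisotropy. Includes a generator of ideal helical
    structures with planted shielding tensors for validation, and readers
    and writers for PDB, mmCIF and MAGRES files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
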