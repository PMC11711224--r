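Package: slabtraj
Title: Trajectory Analysis of Proteins at Liquid-Liquid Slab Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of particle trajectories from biphasic (water/organic)
    slab systems with adsorbed proteins. Locates the solvent-solvent
    interface per frame by a cross-solvent proximity-histogram method with a
    Gibbs dividing surface construction as reference, tracks protein
    centre-of-mass distance to the interface, classifies adsorption
    orientation against a six-pose reference library, computes RMSD/RMSF and
    spreading metrics resolved by distance regime, estimates interfacial
    surface tension from diagonal pressure-tensor series (with the
    Girifalco-Good interaction parameter), and maps per-residue contact
    frequencies over docked-complex ensembles. Includes synthetic slab,
    pressure-series and ensemble generators with machine-readable ground
    truth so every stage is testable without molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'geometry-core.R'
    'AllClasses.R'
    'accessors.R'
    'interface.R'
    'protein-geometry.R'
    'conformation.R'
    'io.R'
    'contacts.R'
    'thermo.R'
    'synthetic.R'
    'pipeline.R'
    'slabtraj-package.R'
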