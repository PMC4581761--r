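Package: gfdyn
Title: Glycoform Trajectory Analysis and MM-GBSA Energetics for
    Hormone-Receptor Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for comparing glycoforms of a two-chain
    protein hormone bound to its receptor from molecular dynamics
    trajectories. Provides rigid-body (Kabsch) superposition with RMSD
    time series and residue shift classification, per-residue RMSF
    profiles with difference flagging and flexibility colour bands,
    interface salt-bridge enumeration with median-distance and
    occupancy statistics, Shrake-Rupley solvent-accessible surface
    area with trajectory averaging and per-residue differencing, and
    an MM-GBSA free-energy engine (molecular-mechanics terms,
    Generalized-Born polar solvation with HCT and OBC-II effective
    radii, SASA-linear nonpolar term) with snapshot averaging and a
    component ledger. A seeded synthetic-complex generator produces
    toy two-chain systems and trajectories with known fluctuation
    amplitudes, conformational-shift events, planted salt bridges and
    pseudo-glycan occluders, so every stage is testable end to end. A
    pipeline driver orchestrates the full glycoform comparison from a
    YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'structure-io.R'
    'sasa.R'
    'energetics.R'
    'superposition.R'
    'fluctuation.R'
    'synthetic-data.R'
    'saltbridges.R'
    'pipeline.R'
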