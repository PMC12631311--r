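Package: mutadyn
Title: Structural Characterization of Point Mutations from Trajectories,
    Spectra and Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for characterizing how a point mutation
    reshapes a protein domain, built around the alsin VPS9 R1611W case
    study. Provides a light structure/trajectory data model with PDB
    input and output, Kabsch superposition and RMSD series,
    Shrake-Rupley accessible surface areas, sequence masses, beta-RMSD
    and probe-loop distance collective variables, Kabsch-Sander
    secondary-structure assignment with per-residue probabilities,
    geometric noncovalent-interaction fingerprints with occupancy
    filtering, block-averaged free-energy surfaces by Boltzmann
    inversion with propagated errors, circular-dichroism
    post-processing and basis-set deconvolution, size-exclusion
    chromatography calibration and oligomer-state assignment, and
    seeded synthetic-data generators with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
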