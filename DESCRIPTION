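Package: pocketscreen
Title: Structure-Guided Virtual Screening, Degron Scanning and TMT
    Proteomics Post-Processing for Deubiquitinase Drug Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for AI-guided structure-based virtual
    screening and its downstream biology: compound library standardization
    with property and substructure (PAINS-style) filters, flood-fill binding
    site definition on protein structures, rigid-body pose ensemble
    generation, multichannel voxel-grid featurization, a 3D convolutional
    affinity scorer with Boltzmann-weighted pose aggregation, ranking and
    MaxMin diversity selection, SPOP-degron motif scanning of protein
    sequences, and TMT reporter-ion normalization with differential protein
    abundance and target-list overlap analysis. Includes seeded synthetic
    generators (toy pockets, fragment-grammar ligand libraries, contact-count
    affinity oracles, planted-effect TMT matrices) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    jsonlite,
    withr,
    Matrix,
    ggplot2,
    generics,
    igraph,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    readr
Config/testthat/edition: 3
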