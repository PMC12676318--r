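Package: hitfunnel
Title: Post-Docking Hit Triage for Structure-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for triaging virtual-screening hits
    after molecular docking. Implements drug-likeness gating (Lipinski rule
    of five plus PAINS and Brenk structural alerts), 3D pharmacophore
    perception and distance-consistent matching, ROC/AUC enrichment
    validation against property-matched decoys, symmetry-corrected docking
    pose RMSD with optional Kabsch superposition, a quadrant filter and
    ideal-point Euclidean ranking of hits on (affinity, LD50), BOILED-Egg
    permeability classification, homology-model quality metrics (sequence
    identity/coverage, backbone dihedrals, Ramachandran classification),
    and molecular-dynamics trajectory stability metrics (RMSD, RMSF,
    geometric hydrogen-bond counts, interaction-energy ratios). Every stage
    is backed by deterministic synthetic-data generators so the full
    pipeline runs and tests without external services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    igraph,
    pracma,
    Biostrings,
    bio3d,
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
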