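Package: synthbind
Title: Synthetic Protein-Ligand Benchmarks for Virtual-Screening Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates synthetic protein-ligand complexes by surrounding 3D
    ligands with randomly sampled typed pharmacophore point clouds and
    labelling each complex with a deterministic binding rule (a 4 Angstrom
    polar-contact rule, or a cumulative Gamma(4,1)-shaped interaction score).
    Because the binding rule is known exactly, the ground-truth contribution
    of every ligand atom is known, and any virtual-screening model's per-atom
    attributions can be scored against it. Includes Morgan and protein-ligand
    extended-connectivity (PLEC-style) fingerprint featurizers, random-forest
    baseline models with atom-masking attributions, ranking-based attribution
    metrics (Attribution AUC, MATR curves, RER), bias-matched dataset
    construction, and end-to-end benchmark workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    Matrix,
    bio3d,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
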