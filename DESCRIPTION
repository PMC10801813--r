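Package: afmscreen
Title: Interface Confidence Scoring and Ranking for AlphaFold-Multimer
    Interaction Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores predicted protein complexes from AlphaFold-Multimer style
    pipelines and ranks candidate interactors in proteome-wide in silico
    screens. Reads predicted coordinate files (PDB or mmCIF, with per-residue
    pLDDT in the temperature-factor field) and predicted-aligned-error (PAE)
    matrices (ColabFold or AFDB JSON dialects), detects inter-chain residue
    contacts under a three-filter definition (pair-average pLDDT, minimum
    directional PAE, minimum heavy-atom distance), computes per-prediction
    interface statistics and pDockQ, aggregates contacts across model
    ensembles into cross-model agreement metrics (avg_n_models and
    max_n_models), filters candidate proteomes by sequence length and
    redundancy, and produces ranked candidate tables with optional
    annotation-based re-ranking. Includes a synthetic-fixture generator that
    plants analytically known interfaces so every stage is testable without
    structure-prediction hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    Biostrings,
    methods,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
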