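Package: essint
Title: Assembly and Structure-Based Scoring of Bacterial Essential Interactomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds candidate interactomes of essential bacterial proteins from
    multi-species essentiality tables, ortholog maps and STRING-format edge
    lists; scores predicted binary complexes with structure-aware confidence
    metrics (pDockQ, pDockQ2, ipTM triage); analyses complex interfaces
    (contact/interface/surface residue sets, Shrake-Rupley solvent-accessible
    surface area, buried interface area, conservation contrasts, residue-type
    contact networks); validates models against reference structures (Kabsch
    superposition, interface RMSD, Fnat, DockQ, TM-score, crosslink distance
    restraints); and assembles the resulting interaction graph with
    Cytoscape-compatible exports. A seeded synthetic-data generator produces
    every input class the pipeline consumes, with known ground truth, so all
    stages are testable without structure-prediction runs or database
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
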