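Package: molevolve
Title: Evolutionary Generation and Optimisation of Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential de novo molecular generation by an evolutionary
    (hill-climbing) algorithm acting directly on molecular graphs with implicit
    hydrogens. Seven atom-level mutation operators (append atom, remove atom,
    change bond, substitute atom type, insert carbon, cut atom, move group) are
    enumerated under a priori validity filters so that every generated molecule
    is connected, respects valence rules, and is unique in the population by
    canonical aromatic SMILES. Ships drug-likeness and synthesizability
    objectives (QED, synthetic-accessibility score, penalised logP with optional
    z-score normalisation, shingle-based ChEMBL-likeness), sigmoid-composed
    multi-objectives, hard-constraint wrappers and an external-evaluator
    contract, and records the whole search as an interpretable exploration tree
    exportable to DOT and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    processx,
    tibble,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
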