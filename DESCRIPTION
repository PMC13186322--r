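Package: orthocellmap
Title: Cross-Species Cell-Type Homology Mapping from Orthogroup Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing cell types across species from single-cell
    expression data. Gene-level counts are collapsed onto orthogroups
    ("ortho-genes") using an OrthoFinder-style assignment table, summarized
    into per-cell-type geometric-mean profiles and pseudocount-regularized
    fold-change matrices, and compared across species with Kullback-Leibler
    divergence; the most similar cross-species cell-type pairs are retained
    by a percentile threshold. Shared orthologous markers for linked cell
    types are called with rank-sum tests and intersected across species.
    Binary orthogroup-activity traits are placed on a dated species tree and
    ancestral states reconstructed by unit-cost maximum parsimony, yielding
    per-branch gain/loss counts and change rates per million years. A
    synthetic multi-species single-cell generator with planted conserved and
    lineage-specific modules and planted trait histories provides ground
    truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
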