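Package: dynappi
Title: Pharmacophore Screening, Titration Fitting and Ensemble Analysis for
    Dynamic Protein-Protein Interaction Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for discovering small-molecule modulators
    of dynamic protein-protein interaction sites, built around the SxIP-EB1
    recruiting interaction. Provides pharmacophore-model construction from
    protein-peptide complexes, combinatorial feature-subset screening of
    conformer libraries with least-squares superposition RMSD filtering,
    multi-objective compound prioritisation (consensus scoring, ligand
    efficiency, Lipinski profiling, Pareto non-dominated sorting), NMR
    chemical-shift-perturbation titration analysis with two-state
    fast-exchange dissociation-constant fitting, receptor-ensemble docking
    score aggregation with rank-concordance statistics, and binding-pocket
    dynamics metrics (gate distances, RMSF, open/closed state
    classification). Seeded synthetic-data generators with machine-readable
    ground truth support end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    minpack.lm,
    graphics,
    jsonlite,
    seqinr,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
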