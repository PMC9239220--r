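Package: fluxContext
Title: Omics-Contextualized Constraint-Based Metabolic Modeling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates gene-level omics (chromatin accessibility or
    expression) into genome-scale metabolic models. Provides
    gene-protein-reaction (GPR) rule parsing and min/max evaluation,
    flux balance analysis (FBA) and a parsimonious two-stage FBA,
    GIMME context-specific model extraction with intersection/union
    combinatory models, differential flux inference from significant
    gene fold changes (consistency-maximizing MILP followed by an
    L2-minimizing QP), flux-prediction evaluation (Pearson r, MSE,
    Fisher-z comparison of correlations, hierarchical clustering of
    samples), and a seeded synthetic-data generator producing
    mass-balanced toy networks, phase-structured dual-channel omics
    and noisy measured fluxes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    quadprog,
    xml2,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: GLPK (the glpsol command-line solver)
Config/testthat/edition: 3
biocViews: Metabolomics, Transcriptomics, Epigenetics, Network, Software
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
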