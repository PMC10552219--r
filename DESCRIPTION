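Package: spatialTME
Title: Spatial Immune Microenvironment Scoring and Outcome Association
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the tumor immune microenvironment from
    multiplex-immunofluorescence cell segmentation tables and relating it to
    clinical outcome. Implements phenotype gating of binary marker calls,
    quadrat-based Morisita-Horn colocalization on a fixed micrometer grid,
    the nearest-neighbor distance distribution G(r) with its Spatial
    Proximity Score summary and the derived Ecoscore classification,
    mean-centered gene-signature scoring, and a per-unit Cox/logistic
    association screen with likelihood-ratio p-values, subgroup and
    adjustment logic, Benjamini-Hochberg correction, tertile Kaplan-Meier
    curves and paired primary-versus-metastasis contrasts. A synthetic-data
    module simulates two-type clustered point patterns, signature-structured
    expression matrices and proportional-hazards outcomes so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
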