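Package: connectotype
Title: Connection-Type-Specific Structural Connectome Analysis and
    Imaging Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking connection-type-specific white-matter
    connectivity loss to regional gene-expression patterns. Partitions a
    group-averaged structural connectome into cortical modules by consensus
    Louvain clustering, classifies connections as interhemispheric,
    intrahemispheric, intramodular or subcortical-cortical, scores
    control-normalised white-matter loss, contrasts patient groups per
    connection class with covariates and FDR control, relates loss to
    streamline length and topological distance, regresses regional gene
    expression on regional loss maps by partial least squares with
    spin-permutation significance and bootstrap gene-weight stability, and
    tests ranked gene lists for expression-weighted cell-type enrichment and
    hypergeometric gene-set overlap. Includes a synthetic-data generator that
    emulates the full study design so every stage can be exercised and
    validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    fgsea,
    lme4,
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
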