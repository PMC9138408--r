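Package: etplineage
Title: Hub-Gene Discovery and Personalized Lineage-Bias Scoring for ETP-ALL Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for early T-cell precursor acute lymphoblastic
    leukemia (ETP-ALL) transcriptomes. Implements two-group differential
    expression with Benjamini-Hochberg false-discovery-rate control,
    within-cohort variable-gene selection, confidence-filtered interaction
    networks with Maximal Clique Centrality (MCC) hub ranking, ROC/AUC
    biomarker evaluation with Youden cutoffs and confusion matrices,
    hypergeometric over-representation analysis, and a per-sample lineage
    bias score that references hub-gene expression to the stemness marker
    PROM1 and aggregates it into myeloid, B, T and unidentified lineage
    scores by geometric means. A synthetic-cohort generator with planted
    differential genes, variance-inflated genes, latent lineage labels and
    planted network cliques provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
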