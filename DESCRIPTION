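Package: grnmotifs
Title: TF-Gene-miRNA Regulatory Motif Construction, Integrity Scoring and
    Ranking
Version: 0.1.0
Authors@R:
    person("GRN", "Maintainers", email = "maintainers@grnmotifs.org",
           role = c("aut", "cre"))
Description: Builds three-node gene regulatory network (GRN) motifs from
    evidence-filtered transcription factor, gene and microRNA interactions,
    confirms them by Pearson co-expression on control samples, classifies
    each (TF, gene, miRNA) trio into one of four motif types (closed-loop,
    common-gene, common-TF, common-miRNA), scores each motif's regulatory
    strength per disease condition with a weighted integrity score, ranks
    motifs by regulatory fold change between disease and control, assigns
    pathways by intersecting the annotations of the three components, and
    validates direction calls against qPCR 2^-dCt relative expression.
    Includes a seed-deterministic synthetic-data generator that emulates
    paired gene/miRNA expression cohorts with planted, differentially
    regulated motifs for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
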