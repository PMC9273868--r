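Package: alstargets
Title: Multi-Cohort Target Prioritization and Retrospective Validation for ALS Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workbench for AI-platform-style therapeutic target
    discovery in amyotrophic lateral sclerosis (ALS). Implements per-comparison
    differential effects on log2 expression, pooling of case-control
    comparisons into subtype/modality meta-analysis groups, directional
    consistency of log fold changes, rank-aggregated metascores with a
    druggability/novelty filter cascade, retrospective "time machine"
    validation of gene rankings (enrichment log fold change and hypergeometric
    tail metrics against a clinical-trial chronology), pathway activation
    scoring with an 80%-unidirectionality dysregulation caller, hierarchical
    hypergeometric process enrichment with Bonferroni correction, gene-set
    similarity networks, and the Drosophila eye-degeneration modifier-screen
    scoring scale. Ships a synthetic study generator with planted truth and
    fixtures transcribed from the source study's summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
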