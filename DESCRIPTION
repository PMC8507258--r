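Package: mircons
Title: Multi-Cohort miRNA Biomarker Discovery with Consensus Differential
    Expression, Target Networks and Survival Panel Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrated pipeline for discovering miRNA biomarkers across
    multiple expression cohorts. Implements per-cohort two-group differential
    testing with a normality-driven test-selection policy and
    Benjamini-Hochberg false discovery control, cross-cohort consensus calling
    with direction-consistency filtering, crossing of candidate miRNAs with
    validated miRNA-target interactions and disease gene lists,
    expression-correlation analysis with Mukaka strength classification,
    hypergeometric pathway enrichment, per-miRNA diagnostic ROC evaluation
    with the Greiner accuracy bins, and exhaustive combinatorial screening of
    prognostic miRNA panels under a concordant-median grouping rule using
    Kaplan-Meier/log-rank tests and Cox proportional-hazards models. Includes
    a synthetic multi-cohort data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
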