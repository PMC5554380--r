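Package: mirct
Title: Serum miRNA Ct-Matrix Normalization, Differential Expression and
    Single-Marker Biomarker Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for TaqMan low-density-array (TLDA) style
    cycle-threshold (Ct) matrices of circulating serum miRNAs. Implements
    flagged-well-aware reference profiles and correlation-ranked endogenous
    control selection, top-k stable-control delta-Ct normalization with
    2^-ddCt fold changes, SAM-style two-class permutation differential
    expression, normality-gated group comparison (one-way ANOVA with Tukey
    multiple comparisons), a mean +/- 2 SD outlier screen, normality-gated
    clinical-score correlation with Bonferroni, Holm and Benjamini-Hochberg
    corrections, and single-marker biomarker evaluation by ROC/Youden
    analysis, repeated random sub-sampling cross-validation and permutation
    testing on AUC. Includes degree-centrality reporting on first-neighbor
    gene networks and hypergeometric over-representation analysis, plus a
    synthetic-cohort generator so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
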