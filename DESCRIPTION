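Package: afproteo
Title: Gestational-Age Modulation Analysis of the Amniotic Fluid Proteome
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for cross-sectional analysis of
    aptamer-based amniotic fluid proteomic data across gestation:
    hybridization/median/plate normalization of relative fluorescence
    units, covariate-adjusted differential abundance with
    empirical-Bayes moderated t-statistics, principal-component
    summaries, signed weighted correlation-network modules (biweight
    midcorrelation and topological overlap), hypergeometric gene-set
    over-representation against the assay panel, tissue-specific
    signature Z-scoring, cross-omics fold-change concordance, and
    cohort demographic statistics. A synthetic-data generator with
    planted ground truth supports end-to-end recovery testing without
    access to clinical data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
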