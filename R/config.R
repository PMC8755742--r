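#' Pipeline configuration
#'
#' Collects every fixed analysis constant in one validated list. Defaults
#' are the thresholds of the published design: significance at q < 0.1 with
#' fold change >= 1.5 for differential abundance, q < 0.05 for enrichment
#' and tissue comparisons, a signed network at soft-threshold power 22, the
#' 30-fold tissue-specificity rule capped at the top 20 genes per tissue,
#' and gene-set terms retained only with at least three hits.
#'
#' @param fc_min minimum fold change (linear scale) for a differential call.
#' @param q_de FDR threshold for differential abundance.
#' @param q_enrich FDR threshold for gene-set over-representation.
#' @param q_tissue FDR threshold for tissue-signature comparisons.
#' @param network_power soft-threshold exponent beta of the signed adjacency.
#' @param specificity_ratio fold-over-other-tissues ratio defining a
#'   tissue-specific gene.
#' @param signature_top_n cap on genes per tissue signature.
#' @param min_term_hits minimum query hits for a gene-set term to be tested.
#' @param min_module_size smallest cluster kept as a module; smaller
#'   clusters fall into the background/noise module (label 0).
#' @param module_merge_corr eigenprofile correlation above which two
#'   modules are merged.
#' @param cut_height tree-cut height for module detection; `NULL` selects
#'   the 99th percentile of the dendrogram merge heights.
#' @param loess_span span of the LOESS gestational-age profiles.
#' @param rng_seed seed used by `run_pipeline()`.
#' @param strict_metadata enforce gestational-age windows on ingest.
#' @return a list of class `af_config`.
#' @export
af_config <- function(fc_min = 1.5, q_de = 0.1, q_enrich = 0.05,
                      q_tissue = 0.05, network_power = 22,
                      specificity_ratio = 30, signature_top_n = 20,
                      min_term_hits = 3, min_module_size = 20,
                      module_merge_corr = 0.85, cut_height = NULL,
                      loess_span = 0.75, rng_seed = 1L,
                      strict_metadata = TRUE) {
  cfg <- list(fc_min = fc_min, q_de = q_de, q_enrich = q_enrich,
              q_tissue = q_tissue, network_power = network_power,
              specificity_ratio = specificity_ratio,
              signature_top_n = signature_top_n,
              min_term_hits = min_term_hits,
              min_module_size = min_module_size,
              module_merge_corr = module_merge_corr,
              cut_height = cut_height, loess_span = loess_span,
              rng_seed = as.integer(rng_seed),
              strict_metadata = isTRUE(strict_metadata))
  thr <- c(cfg$fc_min, cfg$q_de, cfg$q_enrich, cfg$q_tissue,
           cfg$specificity_ratio, cfg$loess_span)
  if (any(!is.finite(thr)) || any(thr <= 0))
    stop("all thresholds must be positive and finite")
  if (cfg$network_power < 1) stop("network_power must be >= 1")
  if (cfg$signature_top_n < 1) stop("signature_top_n must be >= 1")
  if (cfg$min_term_hits < 0) stop("min_term_hits must be >= 0")
  class(cfg) <- "af_config"
  cfg
}
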