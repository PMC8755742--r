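#' Harmonize differential results with a prior-study table
#'
#' Matches analytes of a differential result table to the rows of an
#' external differential table by upper-cased gene symbol. Multi-gene
#' analytes match if any mapped symbol matches; an analyte matching
#' multiple prior rows keeps every pair, flagged with its multiplicity.
#'
#' @param de differential result table
#'   (see [run_differential_abundance()]).
#' @param annotation analyte annotation.
#' @param prior data.frame with `gene`, `log2_fc`, `significant`.
#' @return data.frame of matched pairs: `analyte_id`, `gene`,
#'   `log2_fc_own`, `significant_own`, `log2_fc_prior`,
#'   `significant_prior`, `multiplicity`.
#' @export
harmonize_ids <- function(de, annotation, prior) {
  if (!nrow(de) || !nrow(prior)) stop("empty input table")
  prior$gene <- toupper(as.character(prior$gene))
  if (anyDuplicated(prior$gene))
    stop("duplicate gene ids in the prior table")
  symbols <- split_symbols(
    annotation$gene_symbols[match(de$analyte_id, annotation$analyte_id)])
  pairs <- lapply(seq_len(nrow(de)), function(i) {
    hit <- which(prior$gene %in% symbols[[i]])
    if (!length(hit)) return(NULL)
    data.frame(analyte_id = de$analyte_id[i], gene = prior$gene[hit],
               log2_fc_own = de$log2_fc[i],
               significant_own = de$significant[i],
               log2_fc_prior = prior$log2_fc[hit],
               significant_prior = prior$significant[hit],
               multiplicity = length(hit), stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs))
    stop("no overlap between studies; own symbols look like '",
         symbols[[1]][1], "', prior ids like '", prior$gene[1], "'")
  pairs
}

#' Cross-omics fold-change concordance
#'
#' Restricts matched pairs to molecules significant in both studies (by
#' default), then reports the Spearman correlation of the log2 fold
#' changes and the same-direction fraction (pairs whose fold changes
#' share a nonzero sign; a zero fold change counts as disagreement).
#'
#' @param pairs matched-pair table from [harmonize_ids()].
#' @param require_both_significant filter to pairs significant in both
#'   studies.
#' @return list of class `af_concordance`: `n_common`, `rho`, `p`,
#'   `same_direction_n`, `same_direction_fraction`, `pairs`.
#' @export
concordance <- function(pairs, require_both_significant = TRUE) {
  if (require_both_significant)
    pairs <- pairs[pairs$significant_own & pairs$significant_prior, ,
                   drop = FALSE]
  if (nrow(pairs) < 3)
    stop("fewer than 3 pairs after the significance filter")
  a <- pairs$log2_fc_own
  b <- pairs$log2_fc_prior
  exact <- !any(duplicated(a)) && !any(duplicated(b))
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = exact))
  same <- sign(a) == sign(b) & sign(a) != 0
  structure(list(n_common = nrow(pairs),
                 rho = unname(ct$estimate), p = ct$p.value,
                 same_direction_n = sum(same),
                 same_direction_fraction = mean(same),
                 pairs = pairs),
            class = "af_concordance")
}

#' @export
print.af_concordance <- function(x, ...) {
  cat(sprintf("concordance over %d molecules significant in both studies\n",
              x$n_common))
  cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n", x$rho, x$p))
  cat(sprintf("  same direction: %d/%d (%.1f%%)\n", x$same_direction_n,
              x$n_common, 100 * x$same_direction_fraction))
  invisible(x)
}
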