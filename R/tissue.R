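#' Build tissue-specific signatures from an expression atlas
#'
#' A gene is specific to a tissue when its atlas expression there is at
#' least `specificity_ratio` times the median (or maximum, by flag) of its
#' expression over the remaining tissues. Signatures are intersected with
#' the assay-panel genes and capped at the `top_n` genes with the highest
#' specificity ratio (ties broken by gene name). Tissues ending up with no
#' panel-measured specific gene are excluded with a warning.
#'
#' @param atlas genes x tissues matrix (see [read_tissue_atlas()]).
#' @param panel_genes genes measurable on the panel.
#' @param specificity_ratio fold threshold (default 30).
#' @param top_n signature size cap (default 20).
#' @param comparator summary of the other tissues: `"median"` or `"max"`.
#' @return named list of data.frames (`gene`, `ratio`), one per tissue,
#'   sorted by descending ratio.
#' @export
build_tissue_signatures <- function(atlas, panel_genes,
                                    specificity_ratio = 30, top_n = 20,
                                    comparator = c("median", "max")) {
  comparator <- match.arg(comparator)
  if (ncol(atlas) < 2) stop("atlas requires at least 2 tissues")
  rownames(atlas) <- toupper(rownames(atlas))
  panel_genes <- unique(toupper(panel_genes))
  cmp <- if (comparator == "median") stats::median else max
  sigs <- list()
  for (t in seq_len(ncol(atlas))) {
    other <- apply(atlas[, -t, drop = FALSE], 1, cmp)
    own <- atlas[, t]
    ratio <- ifelse(other == 0, ifelse(own > 0, Inf, 0), own / other)
    specific <- which(ratio >= specificity_ratio)
    genes <- intersect(rownames(atlas)[specific], panel_genes)
    if (!length(genes)) {
      warning("tissue '", colnames(atlas)[t],
              "' has no panel-measured specific gene; excluded")
      next
    }
    r <- ratio[genes]
    ord <- order(-r, genes)
    keep <- utils::head(ord, top_n)
    sigs[[colnames(atlas)[t]]] <- data.frame(gene = genes[keep],
                                             ratio = unname(r[keep]),
                                             stringsAsFactors = FALSE)
  }
  sigs
}

#' Score tissue signatures per sample
#'
#' Standardizes each signature analyte against the reference group
#' (midtrimester): Z = (value - reference mean) / reference SD, then
#' averages the Z-scores of a tissue's signature analytes within each
#' sample. Analytes with zero reference SD are dropped with a warning. A
#' multi-gene analyte contributes to a tissue when any of its mapped
#' symbols is a signature member, and is counted once per tissue.
#'
#' @param x log2-scale [af_abundance()].
#' @param signatures output of [build_tissue_signatures()].
#' @param annotation analyte annotation (for gene mapping).
#' @param metadata sample metadata.
#' @param reference_group group defining the standardization reference.
#' @return samples x tissues matrix of mean Z-scores.
#' @export
score_tissue_signatures <- function(x, signatures, annotation, metadata,
                                    reference_group = "midtrimester") {
  v <- unclass(x)
  ref_samples <- metadata$sample_id[metadata$group == reference_group]
  ref_samples <- intersect(ref_samples, rownames(v))
  if (length(ref_samples) < 2) stop("reference group needs >= 2 samples")
  symbols <- split_symbols(annotation$gene_symbols)
  scores <- matrix(NA_real_, nrow(v), length(signatures),
                   dimnames = list(rownames(v), names(signatures)))
  dropped <- 0L
  for (t in names(signatures)) {
    members <- signatures[[t]]$gene
    hit <- vapply(symbols, function(s) any(s %in% members), logical(1))
    analytes <- intersect(annotation$analyte_id[hit], colnames(v))
    if (!length(analytes)) stop("empty signature after matrix intersection: ", t)
    sub <- v[, analytes, drop = FALSE]
    mu <- colMeans(sub[ref_samples, , drop = FALSE])
    sd <- apply(sub[ref_samples, , drop = FALSE], 2, stats::sd)
    ok <- sd > 0
    dropped <- dropped + sum(!ok)
    if (!any(ok)) stop("all signature analytes have zero reference SD: ", t)
    z <- sweep(sweep(sub[, ok, drop = FALSE], 2, mu[ok]), 2, sd[ok], "/")
    scores[, t] <- rowMeans(z)
  }
  if (dropped > 0)
    warning(dropped, " signature analyte(s) dropped (zero reference SD)")
  scores
}

#' Compare tissue scores between groups
#'
#' Wilcoxon rank-sum test of the per-sample tissue Z-scores between term
#' and midtrimester: exact two-sided p when both groups have at most 25
#' samples and there are no ties, normal approximation with tie
#' correction otherwise; BH adjustment across tissues. Direction is the
#' sign of the term-minus-midtrimester median difference.
#'
#' @param scores samples x tissues matrix from
#'   [score_tissue_signatures()].
#' @param metadata sample metadata.
#' @param q_tissue FDR threshold for the `significant` flag.
#' @return data.frame: `tissue`, `median_mid`, `median_term`, `W`, `p`,
#'   `q`, `direction`, `significant`.
#' @export
compare_tissue_scores <- function(scores, metadata, q_tissue = 0.05) {
  grp <- metadata$group[match(rownames(scores), metadata$sample_id)]
  mid <- grp == "midtrimester"
  out <- lapply(colnames(scores), function(t) {
    a <- scores[!mid, t]  # term
    b <- scores[mid, t]   # midtrimester reference
    if (length(a) < 2 || length(b) < 2) stop("both groups need >= 2 samples")
    if (stats::sd(c(a, b)) == 0) stop("constant scores in both groups: ", t)
    exact <- length(a) <= 25 && length(b) <= 25 &&
      !any(duplicated(c(a, b)))
    ht <- stats::wilcox.test(a, b, exact = exact, correct = !exact)
    data.frame(tissue = t,
               median_mid = stats::median(b),
               median_term = stats::median(a),
               W = unname(ht$statistic), p = ht$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- bh_adjust(out$p)
  out$direction <- ifelse(out$median_term - out$median_mid >= 0,
                          "increased", "decreased")
  out$significant <- out$q < q_tissue
  out
}
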