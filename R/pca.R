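#' Principal-component summary of the proteome
#'
#' Singular value decomposition of the (optionally) column-centered and
#' unit-scaled log2 matrix. Zero-variance analytes are dropped (and
#' recorded) when unit scaling is requested. Component signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param x log2-scale [af_abundance()] or numeric matrix (samples x
#'   analytes).
#' @param center,unit_scale column standardization flags.
#' @param n_components number of components to retain (default: full rank).
#' @return list of class `af_pca`: `scores` (samples x components),
#'   `loadings` (analytes x components, orthonormal), `variance_fraction`,
#'   `dropped` (zero-variance analytes).
#' @export
compute_pca <- function(x, center = TRUE, unit_scale = TRUE,
                        n_components = NULL) {
  v <- if (inherits(x, "af_abundance")) unclass(x) else as.matrix(x)
  if (nrow(v) < 2) stop("PCA requires at least 2 samples")
  dropped <- character(0)
  if (unit_scale) {
    sds <- apply(v, 2, stats::sd)
    dropped <- colnames(v)[sds == 0]
    v <- v[, sds > 0, drop = FALSE]
  }
  v <- scale(v, center = center, scale = unit_scale)
  full <- min(dim(v))
  if (is.null(n_components)) n_components <- full
  if (n_components > full) stop("n_components exceeds matrix rank bound")
  sv <- svd(v)
  k <- seq_len(n_components)
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components)
  loadings <- sv$v[, k, drop = FALSE]
  for (j in k) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(v), paste0("PC", k))
  dimnames(loadings) <- list(colnames(v), paste0("PC", k))
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = (sv$d^2 / sum(sv$d^2))[k],
                 singular_values = sv$d, dropped = dropped),
            class = "af_pca")
}

#' Correlation of a principal component with a sample trait
#'
#' Pearson correlation (with two-sided p) between a score vector and a
#' trait such as gestational age. Because a component's sign is an
#' arbitrary convention, `abs_r` is reported alongside the signed value.
#'
#' @param scores numeric score vector (one component).
#' @param trait numeric trait of equal length, nonconstant.
#' @return list with `r`, `abs_r`, `p`, `n`.
#' @export
pc_trait_correlation <- function(scores, trait) {
  if (length(scores) != length(trait)) stop("length mismatch")
  if (stats::sd(trait) == 0) stop("trait is constant")
  ct <- stats::cor.test(scores, trait, method = "pearson")
  list(r = unname(ct$estimate), abs_r = abs(unname(ct$estimate)),
       p = ct$p.value, n = length(trait))
}
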