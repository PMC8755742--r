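#' Biweight midcorrelation matrix
#'
#' Robust correlation between analyte profiles: deviations from the median
#' are downweighted by Tukey biweights `(1 - u^2)^2` with `u =
#' (x - median) / (9 * MAD)` (unscaled MAD, tuning constant 9), and
#' observations beyond 9 MADs receive zero weight. Analytes with zero MAD
#' cannot be weighted this way and fall back to mean-centering (their
#' correlations reduce to Pearson), with a warning.
#'
#' @param x log2-scale [af_abundance()] or numeric matrix (samples x
#'   analytes), at least 4 samples.
#' @return symmetric analyte x analyte correlation matrix with unit
#'   diagonal.
#' @export
bicor_matrix <- function(x) {
  v <- if (inherits(x, "af_abundance")) unclass(x) else as.matrix(x)
  if (nrow(v) < 4) stop("bicor requires at least 4 samples")
  w <- apply(v, 2, bicor_prepare)
  fallback <- attr(w, "fallback")
  nz <- sqrt(colSums(w^2))
  bad <- nz == 0
  if (any(bad)) nz[bad] <- 1  # constant columns: correlation undefined -> 0
  w <- sweep(w, 2, nz, "/")
  r <- crossprod(w)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(colnames(v), colnames(v))
  r
}

# median/MAD biweight transform of one profile; mean-centered fallback
# (Pearson) when MAD is zero
bicor_prepare <- function(x) {
  med <- stats::median(x)
  mad <- stats::median(abs(x - med))
  if (mad == 0) return(x - mean(x))
  u <- (x - med) / (9 * mad)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Biweight midcorrelation of two vectors
#' @param x,y numeric vectors of equal length (>= 4).
#' @return scalar correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  bicor_matrix(cbind(a = x, b = y))["a", "b"]
}

#' Signed soft-threshold adjacency
#'
#' Network edge weights `a = ((1 + rho) / 2)^beta`: perfectly correlated
#' pairs get weight 1, perfectly anti-correlated pairs 0, and
#' uncorrelated pairs `0.5^beta` (about 2.4e-7 at the default beta = 22).
#'
#' @param rho correlation matrix with values in `[-1, 1]`.
#' @param beta soft-threshold power (>= 1).
#' @return adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(rho, beta = 22) {
  if (beta < 1) stop("beta must be >= 1")
  if (any(rho < -1 - 1e-12 | rho > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]")
  a <- ((1 + rho) / 2)^beta
  a[a > 1] <- 1; a[a < 0] <- 0
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k` the connectivity (row sum excluding the diagonal); diagonal 1.
#' Combines direct adjacency with shared-neighbor support.
#'
#' @param adjacency symmetric matrix in `[0, 1]`.
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  a <- adjacency
  diag(a) <- 0
  num <- a %*% a + a
  k <- rowSums(a)
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module detection by static tree cut with eigenprofile merging
#'
#' Average-linkage hierarchical clustering on `1 - TOM`. The default cut
#' height is chosen deterministically by scanning the dendrogram merge
#' heights for the cut that maximizes the number of clusters of at least
#' `min_module_size`, breaking ties toward the cut assigning the most
#' analytes. Clusters smaller than `min_module_size` are relabeled 0
#' (background/noise module); modules whose eigenprofiles correlate above
#' `merge_corr` are merged iteratively; finally, background analytes
#' whose correlation with a module eigenprofile (kME) reaches
#' `kme_assign` are assigned to their best-matching module — the
#' analogue of the partitioning stage of hybrid tree cutting, without
#' which tightly nested modules shed members into the background. Final
#' labels are ordered by decreasing module size.
#'
#' @param tom TOM similarity matrix.
#' @param expr log2 matrix (samples x analytes) for eigenprofile merging.
#' @param min_module_size smallest retained module.
#' @param cut_height static cut height on `1 - TOM` (or `NULL` for the
#'   scan described above).
#' @param merge_corr eigenprofile correlation triggering a merge.
#' @param kme_assign minimum kME for rescuing a background analyte into a
#'   module (set above 1 to disable).
#' @param max_height largest admissible TOM dissimilarity for the
#'   automatic cut-height scan.
#' @return data.frame of class `af_modules` with `analyte_id` and
#'   `module` (0 = noise); attribute `n_modules`.
#' @export
detect_modules <- function(tom, expr, min_module_size = 20,
                           cut_height = NULL, merge_corr = 0.85,
                           kme_assign = 0.5, max_height = 0.995) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  if (is.null(cut_height)) {
    ## deterministic height selection: scan candidate cut heights for the
    ## one yielding the most clusters of admissible size, so nested
    ## module structure is not collapsed into one block; ties go to the
    ## cut covering the most analytes. Candidates are capped at a TOM
    ## dissimilarity of max_height: clusters only cohering above it (the
    ## regime of a structureless network at high soft-threshold powers)
    ## are not admissible modules
    cand <- stats::quantile(hc$height, seq(0.5, 0.995, by = 0.005),
                            names = FALSE)
    cand <- cand[cand <= max_height]
    if (!length(cand)) {
      warning("no dendrogram structure below max_height; ",
              "all analytes in the noise module")
      out <- data.frame(analyte_id = colnames(tom), module = 0L,
                        stringsAsFactors = FALSE)
      attr(out, "n_modules") <- 0L
      class(out) <- c("af_modules", "data.frame")
      return(out)
    }
    score <- vapply(cand, function(h) {
      sz <- table(stats::cutree(hc, h = h))
      big <- sz[sz >= min_module_size]
      c(length(big), sum(big))
    }, numeric(2))
    best <- which(score[1, ] == max(score[1, ]))
    cut_height <- cand[best[which.max(score[2, best])]]
  }
  labels <- stats::cutree(hc, h = cut_height)
  sizes <- table(labels)
  labels[labels %in% names(sizes)[sizes < min_module_size]] <- 0L
  if (all(labels == 0)) {
    warning("no module exceeds min_module_size; all analytes in noise module")
    out <- data.frame(analyte_id = colnames(tom), module = 0L,
                      stringsAsFactors = FALSE)
    attr(out, "n_modules") <- 0L
    class(out) <- c("af_modules", "data.frame")
    return(out)
  }
  expr <- as.matrix(expr)[, colnames(tom), drop = FALSE]
  labels <- merge_modules(labels, expr, merge_corr)
  ## rescue background analytes with a strong module eigenprofile match
  if (kme_assign <= 1 && any(labels == 0) && any(labels != 0)) {
    ids <- setdiff(unique(labels), 0)
    eig <- vapply(ids, function(m)
      eigenprofile_of(expr[, labels == m, drop = FALSE])$profile,
      numeric(nrow(expr)))
    kme0 <- stats::cor(expr[, labels == 0, drop = FALSE], eig)
    top <- apply(kme0, 1, which.max)
    ok <- kme0[cbind(seq_along(top), top)] >= kme_assign
    labels[labels == 0][ok] <- ids[top[ok]]
  }
  ## relabel 1..K by decreasing size
  nz <- labels[labels != 0]
  ord <- names(sort(table(nz), decreasing = TRUE))
  relab <- stats::setNames(seq_along(ord), ord)
  labels[labels != 0] <- relab[as.character(nz)]
  out <- data.frame(analyte_id = colnames(tom), module = unname(labels),
                    stringsAsFactors = FALSE)
  attr(out, "n_modules") <- length(ord)
  class(out) <- c("af_modules", "data.frame")
  out
}

merge_modules <- function(labels, expr, merge_corr) {
  repeat {
    ids <- setdiff(unique(labels), 0)
    if (length(ids) < 2) return(labels)
    eig <- vapply(ids, function(m)
      eigenprofile_of(expr[, labels == m, drop = FALSE])$profile,
      numeric(nrow(expr)))
    cc <- stats::cor(eig)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= merge_corr) return(labels)
    labels[labels == ids[mx[2]]] <- ids[mx[1]]
  }
}

# first principal component of a module's standardized member profiles,
# oriented so the mean member correlation is nonnegative
eigenprofile_of <- function(member_expr) {
  m <- as.matrix(member_expr)
  if (ncol(m) == 1) {
    v <- drop(scale(m))
    prof <- v / sqrt(sum(v^2))
    return(list(profile = prof, var_explained = 1, singleton = TRUE))
  }
  sds <- apply(m, 2, stats::sd)
  sds[sds == 0] <- 1
  z <- scale(m, scale = sds)
  sv <- svd(z, nu = 1, nv = 0)
  prof <- sv$u[, 1]
  if (mean(stats::cor(m, prof)) < 0) prof <- -prof
  list(profile = prof, var_explained = sv$d[1]^2 / sum(sv$d^2),
       singleton = FALSE)
}

#' Module eigenprofiles and kME
#'
#' For each module, the eigenprofile is the first principal component of
#' the standardized member profiles (unit norm, oriented so the mean
#' member correlation is nonnegative). kME is the Pearson correlation of
#' every analyte's profile with each module eigenprofile — the hub score.
#'
#' @param expr log2 matrix (samples x analytes).
#' @param assignment an `af_modules` assignment from [detect_modules()].
#' @return list with `eigenprofiles` (samples x modules), `var_explained`,
#'   `kme` (analytes x modules), `singleton` flags.
#' @export
module_eigenprofiles <- function(expr, assignment) {
  expr <- as.matrix(expr)
  ids <- sort(setdiff(unique(assignment$module), 0))
  if (!length(ids)) stop("no nonempty modules")
  profs <- matrix(NA_real_, nrow(expr), length(ids),
                  dimnames = list(rownames(expr), paste0("M", ids)))
  ve <- stats::setNames(numeric(length(ids)), paste0("M", ids))
  singleton <- logical(length(ids))
  for (i in seq_along(ids)) {
    members <- assignment$analyte_id[assignment$module == ids[i]]
    e <- eigenprofile_of(expr[, members, drop = FALSE])
    profs[, i] <- e$profile
    ve[i] <- e$var_explained
    singleton[i] <- e$singleton
  }
  if (any(singleton)) warning("module(s) of size 1: eigenprofile is the ",
                              "single standardized profile")
  kme <- stats::cor(expr[, assignment$analyte_id, drop = FALSE], profs)
  list(eigenprofiles = profs, var_explained = ve, kme = kme,
       singleton = singleton)
}

#' Intra-modular hub selection
#'
#' The `n` members of each module with the highest kME; ties broken by
#' analyte id. Modules smaller than `n` return all members with a
#' warning.
#'
#' @param kme analytes x modules kME matrix from [module_eigenprofiles()].
#' @param assignment module assignment.
#' @param n hubs per module.
#' @return data.frame with `module`, `analyte_id`, `kme`, `rank`.
#' @export
select_hubs <- function(kme, assignment, n = 4) {
  ids <- sort(setdiff(unique(assignment$module), 0))
  out <- lapply(ids, function(m) {
    members <- assignment$analyte_id[assignment$module == m]
    if (length(members) < n)
      warning("module ", m, " smaller than n; returning all members")
    k <- kme[members, paste0("M", m)]
    ord <- order(-k, members)
    top <- utils::head(ord, min(n, length(members)))
    data.frame(module = m, analyte_id = members[top], kme = k[top],
               rank = seq_along(top), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' LOESS gestational-age profile
#'
#' Local quadratic regression with tricube weights of a standardized
#' profile on gestational age, evaluated on an even grid spanning the
#' data range.
#'
#' @param ga gestational ages (>= 5 points).
#' @param y profile values.
#' @param span LOESS span in `(0, 1]`.
#' @param grid_n grid resolution.
#' @return data.frame with `ga` and `fitted`.
#' @export
loess_profile <- function(ga, y, span = 0.75, grid_n = 50) {
  if (length(ga) < 5) stop("LOESS requires at least 5 points")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (span * length(ga) < 4)
    stop("span too small for the local quadratic fit at this sample size")
  fit <- stats::loess(y ~ ga, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(ga), max(ga), length.out = grid_n)
  data.frame(ga = grid, fitted = stats::predict(fit, newdata =
                                                  data.frame(ga = grid)))
}

#' Full network-module stage
#'
#' Runs bicor -> signed adjacency -> TOM -> module detection ->
#' eigenprofiles/kME -> hub selection on a set of analytes (typically the
#' union of differentially abundant proteins from both contrasts).
#'
#' @param x log2-scale [af_abundance()].
#' @param analytes analyte ids entering the network.
#' @param config an [af_config()].
#' @param n_hubs hubs reported per module.
#' @return list with `assignment`, `eigen` (see
#'   [module_eigenprofiles()]), `hubs`, `tom`.
#' @export
run_network_modules <- function(x, analytes = analyte_ids(x),
                                config = af_config(), n_hubs = 4) {
  expr <- unclass(x)[, analytes, drop = FALSE]
  rho <- bicor_matrix(expr)
  adj <- signed_adjacency(rho, beta = config$network_power)
  tom <- topological_overlap(adj)
  assignment <- detect_modules(tom, expr,
                               min_module_size = config$min_module_size,
                               cut_height = config$cut_height,
                               merge_corr = config$module_merge_corr)
  if (attr(assignment, "n_modules") == 0)
    return(list(assignment = assignment, eigen = NULL, hubs = NULL,
                tom = tom))
  eigen <- module_eigenprofiles(expr, assignment)
  hubs <- select_hubs(eigen$kme, assignment, n = n_hubs)
  list(assignment = assignment, eigen = eigen, hubs = hubs, tom = tom)
}
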