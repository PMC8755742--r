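#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table. This is the
#' convention under which the demographic comparisons of a midtrimester
#' versus term cohort (race, smoking, parity, preterm-birth history,
#' cesarean delivery, fetal sex) are reproduced exactly.
#'
#' @param table 2x2 integer matrix of counts (rows = groups,
#'   columns = outcome yes/no), or the count `a` with `b`, `c`, `d`.
#' @param b,c,d remaining cell counts when `table` is given as a scalar.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(2, 11, 9, 6), 2, byrow = TRUE)) # fetal sex
#' @export
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (!is.matrix(table)) table <- matrix(c(table, b, c, d), 2, byrow = TRUE)
  if (!all(dim(table) == 2)) stop("expected a 2x2 table")
  counts <- as.vector(table)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("empty table")
  a <- table[1, 1]
  K <- sum(table[1, ])          # row-1 margin
  n <- sum(table[, 1])          # column-1 margin
  N <- sum(table)
  support <- max(0, n - (N - K)):min(K, n)
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(a, K, N - K, n)
  # relative tolerance guards against ties broken by floating-point error
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Welch's t-test for two independent groups
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' used for continuous demographic variables.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = Inf, p = 1))
    stop("both groups have zero variance with different means")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Demographic summary table with group comparisons
#'
#' Summarizes clinical covariates per group — median (IQR) for continuous
#' variables with a Welch's t-test, count/denominator (%) for binary
#' variables with Fisher's exact test — excluding missing values
#' per variable and reporting how many were missing.
#'
#' @param metadata sample metadata with a two-level `group` column.
#' @param variables data.frame with columns `name` (column in `metadata`),
#'   `type` (`"continuous"` or `"binary"`), and optionally `positive`
#'   (level counted as "yes" for binary variables).
#' @return data.frame with one row per variable: per-group summaries, the
#'   test used, p-value, and missing count.
#' @export
summarize_cohort <- function(metadata, variables) {
  grp <- factor(as.character(metadata$group),
                levels = c("midtrimester", "term"))
  out <- lapply(seq_len(nrow(variables)), function(i) {
    nm <- variables$name[i]
    type <- variables$type[i]
    if (!nm %in% names(metadata)) stop("unknown variable: ", nm)
    v <- metadata[[nm]]
    keep <- !is.na(v)
    vv <- v[keep]; gg <- grp[keep]
    if (type == "continuous") {
      summ <- vapply(levels(gg), function(l) {
        q <- stats::quantile(vv[gg == l], c(0.25, 0.5, 0.75))
        sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
      }, character(1))
      p <- welch_t_test(vv[gg == "midtrimester"], vv[gg == "term"])$p
      test <- "Welch t-test"
    } else if (type == "binary") {
      pos <- if (!is.null(variables$positive)) variables$positive[i] else NA
      yes <- if (is.logical(vv)) vv else vv == pos
      tab <- rbind(c(sum(yes[gg == "midtrimester"]), sum(!yes[gg == "midtrimester"])),
                   c(sum(yes[gg == "term"]), sum(!yes[gg == "term"])))
      summ <- vapply(1:2, function(r) {
        den <- sum(tab[r, ])
        sprintf("%d/%d (%.1f%%)", tab[r, 1], den, 100 * tab[r, 1] / den)
      }, character(1))
      names(summ) <- levels(gg)
      p <- fisher_exact_2x2(tab)
      test <- "Fisher exact"
    } else stop("unknown variable type: ", type)
    data.frame(variable = nm, midtrimester = summ[["midtrimester"]],
               term = summ[["term"]], test = test, p_value = p,
               n_missing = sum(!keep), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
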