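#' Per-analyte covariate-adjusted linear models
#'
#' Fits, by ordinary least squares, one linear model per analyte on the
#' log2 scale: abundance ~ group + covariates. The group coefficient is the
#' log2 fold change (second level minus first). All analytes share the
#' design matrix, so residual degrees of freedom and the unscaled
#' coefficient variance are common.
#'
#' @param x log2-scale [af_abundance()] (or plain matrix, samples x
#'   analytes).
#' @param metadata sample metadata; rows are matched to the matrix by
#'   `sample_id`.
#' @param group name of the two-level factor column defining the contrast.
#' @param covariates character vector of metadata columns adjusted for
#'   (e.g. `c("fetal_sex", "maternal_age_years")`); may be empty.
#' @return list of class `af_fit`: `effects` (named log2 fold changes),
#'   `s2` (residual variances), `df_residual`, `v_unscaled` (unscaled
#'   variance of the group coefficient), `zero_variance` flags, `design`.
#' @export
fit_protein_models <- function(x, metadata, group = "group",
                               covariates = c("fetal_sex",
                                              "maternal_age_years")) {
  v <- if (inherits(x, "af_abundance")) {
    if (abundance_scale(x) != "log2")
      stop("model fitting requires log2-scale data")
    unclass(x)
  } else as.matrix(x)
  idx <- match(rownames(v), metadata$sample_id)
  if (anyNA(idx)) stop("metadata does not cover all samples")
  md <- metadata[idx, , drop = FALSE]
  g <- factor(md[[group]])
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  vars <- c(group, covariates)
  fml <- stats::as.formula(paste("~", paste(vars, collapse = " + ")))
  X <- stats::model.matrix(fml, data = md)
  p <- ncol(X)
  if (nrow(X) <= p) stop("more coefficients than samples")
  if (qr(X)$rank < p)
    stop("rank-deficient design (covariate collinear with the group?)")
  fit <- stats::lm.fit(X, v)
  d <- nrow(X) - p
  res <- as.matrix(fit$residuals)
  s2 <- colSums(res^2) / d
  gcol <- paste0(group, levels(g)[2])
  xtxinv <- solve(crossprod(X))
  v_unscaled <- xtxinv[gcol, gcol]
  zero <- s2 < .Machine$double.eps * 100
  if (any(zero))
    warning(sum(zero), " analyte(s) with ~zero residual variance")
  structure(list(effects = fit$coefficients[gcol, ],
                 s2 = stats::setNames(s2, colnames(v)),
                 df_residual = d, v_unscaled = v_unscaled,
                 zero_variance = zero, design = X,
                 group_levels = levels(g), covariates = covariates),
            class = "af_fit")
}

#' Newton inversion of the trigamma function
#' @param y positive value(s); returns x with trigamma(x) = y.
#' @keywords internal
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(NaN)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-analyte variances
#'
#' Shrinks each analyte's residual variance toward a common prior fitted
#' by method of moments on the log-variances (digamma/trigamma matching),
#' then forms the moderated t-statistic with augmented degrees of freedom
#' d0 + d. With `d0 = 0` the statistic reduces to the ordinary OLS t-test;
#' with all variances equal the fitted `d0` is infinite and the posterior
#' variance equals the prior.
#'
#' @param s2 per-analyte residual variances.
#' @param d shared residual degrees of freedom (>= 1).
#' @param effects per-analyte effect estimates (log2 fold changes).
#' @param v_unscaled unscaled variance of the effect coefficient.
#' @param d0 optional forced prior degrees of freedom (0, a positive
#'   value, or Inf); estimated when `NULL`.
#' @return list with `d0`, `s02`, `s2_post`, `t`, `p`, `df_total`.
#' @export
moderate_empirical_bayes <- function(s2, d, effects, v_unscaled, d0 = NULL) {
  if (any(s2 < 0)) stop("negative variance")
  if (d < 1) stop("residual df must be >= 1")
  if (length(s2) < 10 && is.null(d0))
    stop("fewer than 10 analytes: hyperparameter fit unstable; supply d0")
  if (is.null(d0)) {
    ok <- s2 > 0
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      ## no excess spread in log s^2: variances are exchangeable and the
      ## pooled (arithmetic mean) variance is the common estimate
      d0 <- Inf
      s02 <- mean(s2)
    }
  } else {
    if (d0 < 0) stop("d0 must be >= 0")
    ok <- s2 > 0
    s02 <- if (is.infinite(d0)) {
      mean(s2)
    } else if (d0 == 0) NA_real_ else {
      e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + d * s2) / (d0 + d)
  t <- effects / sqrt(v_unscaled * s2_post)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t), df = df_total)
  list(d0 = d0, s02 = s02, s2_post = s2_post, t = t, p = p,
       df_total = df_total)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p p-values in `[0, 1]`.
#' @return step-up adjusted q-values (monotone in p, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply the significance call rule
#'
#' An analyte is called significant when q < `q_de` (strict) and fold
#' change >= `fc_min` (inclusive); direction follows the sign of the log2
#' fold change.
#'
#' @param de a differential result table (see
#'   [run_differential_abundance()]).
#' @param fc_min,q_de calling thresholds.
#' @return list with the flagged `table`, `n_up`, `n_down`.
#' @export
call_significant <- function(de, fc_min = 1.5, q_de = 0.1) {
  de$significant <- de$q < q_de & de$fold_change >= fc_min
  de$direction <- ifelse(de$log2_fc >= 0, "up", "down")
  list(table = de,
       n_up = sum(de$significant & de$direction == "up"),
       n_down = sum(de$significant & de$direction == "down"))
}

#' Covariate-adjusted moderated differential abundance
#'
#' The full differential stage: per-analyte OLS fits, empirical-Bayes
#' variance moderation, BH adjustment, and the fold-change/q calling rule.
#' Control analytes are excluded. The contrast is either term versus
#' midtrimester, or late versus early midtrimester (samples split at the
#' `boundary` gestational age).
#'
#' @param x log2-scale [af_abundance()].
#' @param metadata sample metadata.
#' @param annotation optional analyte annotation used to drop controls.
#' @param covariates metadata columns adjusted for.
#' @param contrast `"term_vs_mid"` or `"late_vs_early"`.
#' @param config an [af_config()] supplying `fc_min` and `q_de`.
#' @param boundary gestational-age split (weeks) for the midtrimester
#'   contrast.
#' @param d0 optional forced prior df (see [moderate_empirical_bayes()]).
#' @return data.frame (one row per analyte): `analyte_id`, `log2_fc`,
#'   `fold_change` (= 2^|log2_fc|), `direction`, `s2`, `df_residual`,
#'   `t`, `p`, `q`, `significant`; attributes `d0`, `s02`, `covariates`,
#'   `contrast`.
#' @export
run_differential_abundance <- function(x, metadata, annotation = NULL,
                                       covariates = c("fetal_sex",
                                                      "maternal_age_years"),
                                       contrast = c("term_vs_mid",
                                                    "late_vs_early"),
                                       config = af_config(),
                                       boundary = 21.05, d0 = NULL) {
  contrast <- match.arg(contrast)
  if (!is.null(annotation)) {
    keep <- annotation$analyte_id[!annotation$is_control]
    x <- af_abundance(unclass(x)[, intersect(analyte_ids(x), keep),
                                 drop = FALSE],
                      scale = abundance_scale(x))
  }
  if (contrast == "late_vs_early") {
    mid <- metadata[metadata$group == "midtrimester", , drop = FALSE]
    halves <- split_midtrimester(mid, boundary = boundary)
    md <- mid
    md$phase <- factor(ifelse(md$sample_id %in% halves$early,
                              "early", "late"),
                       levels = c("early", "late"))
    x <- af_abundance(unclass(x)[md$sample_id, , drop = FALSE],
                      scale = abundance_scale(x))
    fit <- fit_protein_models(x, md, group = "phase",
                              covariates = covariates)
  } else {
    fit <- fit_protein_models(x, metadata, group = "group",
                              covariates = covariates)
  }
  eb <- moderate_empirical_bayes(fit$s2, fit$df_residual, fit$effects,
                                 fit$v_unscaled, d0 = d0)
  de <- data.frame(analyte_id = names(fit$effects),
                   log2_fc = unname(fit$effects),
                   fold_change = 2^abs(unname(fit$effects)),
                   direction = ifelse(fit$effects >= 0, "up", "down"),
                   s2 = unname(fit$s2),
                   df_residual = fit$df_residual,
                   t = unname(eb$t), p = unname(eb$p),
                   q = bh_adjust(unname(eb$p)),
                   stringsAsFactors = FALSE)
  de <- call_significant(de, config$fc_min, config$q_de)$table
  attr(de, "d0") <- eb$d0
  attr(de, "s02") <- eb$s02
  attr(de, "covariates") <- covariates
  attr(de, "contrast") <- contrast
  de
}

#' Compare two differential analyses (sensitivity analysis)
#'
#' Correlates log2 fold changes of two model variants (e.g. with and
#' without a BMI covariate) over the analytes significant in the
#' reference analysis, and reports the fraction agreeing in direction.
#'
#' @param deA reference result table (defines the significant set).
#' @param deB comparison result table over the same analytes.
#' @return list with `r` (Pearson), `direction_agreement`, `n`.
#' @export
compare_adjustments <- function(deA, deB) {
  idx <- match(deA$analyte_id, deB$analyte_id)
  if (anyNA(idx)) stop("analyte universes differ")
  sig <- which(deA$significant)
  if (!length(sig)) stop("empty significant set in the reference analysis")
  a <- deA$log2_fc[sig]
  b <- deB$log2_fc[idx][sig]
  list(r = stats::cor(a, b),
       direction_agreement = mean(sign(a) == sign(b)),
       n = length(sig))
}

#' Split midtrimester samples into early and late phases
#'
#' Samples at or below the boundary gestational age are "early", the rest
#' "late" (default boundary 21.05 weeks places 21.0 in early and 21.1 in
#' late, matching one-decimal gestational-age precision).
#'
#' @param metadata metadata containing only midtrimester samples.
#' @param boundary split point in weeks.
#' @return list with `early` and `late` sample-id vectors.
#' @export
split_midtrimester <- function(metadata, boundary = 21.05) {
  if (any(metadata$group != "midtrimester"))
    stop("split_midtrimester expects midtrimester samples only")
  ga <- metadata$gestational_age_weeks
  early <- metadata$sample_id[ga <= boundary]
  late <- metadata$sample_id[ga > boundary]
  if (!length(early)) stop("empty early subgroup")
  if (!length(late)) stop("empty late subgroup")
  list(early = early, late = late)
}
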