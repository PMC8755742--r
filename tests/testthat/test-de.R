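toy_log2 <- function() {
  set.seed(1)
  n <- 12
  md <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   group = factor(rep(c("midtrimester", "term"), each = 6),
                                  levels = c("midtrimester", "term")),
                   gestational_age_weeks = c(runif(6, 17, 23),
                                             runif(6, 37, 41)),
                   fetal_sex = factor(rep(c("F", "M"), 6),
                                      levels = c("F", "M")),
                   maternal_age_years = round(runif(n, 20, 38), 1))
  m <- matrix(rnorm(n * 40, 9, 0.5), n, 40,
              dimnames = list(md$sample_id, sprintf("A%02d", 1:40)))
  m[md$group == "term", 1] <- m[md$group == "term", 1] + 1
  list(x = af_abundance(m, "log2"), md = md)
}

test_that("the group coefficient is the adjusted log2 fold change", {
  ## two-group toy with means 8 and 9 and no covariates -> effect 1
  md <- data.frame(sample_id = sprintf("s%d", 1:6),
                   group = rep(c("midtrimester", "term"), each = 3))
  m <- matrix(rep(c(8, 9), each = 3), 6, 2,
              dimnames = list(md$sample_id, c("A1", "A2")))
  m[, 2] <- m[, 2] + c(0.1, -0.1, 0, 0.2, -0.2, 0)
  expect_warning(fit <- fit_protein_models(af_abundance(m, "log2"), md,
                                           covariates = character(0)),
                 "zero residual variance")
  expect_equal(unname(fit$effects[1]), 1, tolerance = 1e-12)
  expect_equal(fit$df_residual, 4)
  expect_equal(fit$v_unscaled, 1 / 3 + 1 / 3, tolerance = 1e-12)

  ## collinear covariate triggers the rank-deficiency error
  md$dup <- as.numeric(md$group == "term")
  expect_error(fit_protein_models(af_abundance(m, "log2"), md,
                                  covariates = "dup"), "rank-deficient")
})

test_that("fold-change estimates are unbiased with OLS-sized errors", {
  errs <- ses <- c()
  for (s in 1:25) {
    sim <- simulate_cohort(small_config(seed = s,
                                        module_sizes = integer(0)))
    tr <- sim$truth
    de <- run_differential_abundance(signal_abundance(sim), sim$metadata,
                                     sim$annotation)
    tt <- truth_of(sim, de)
    isde <- tt$is_de
    errs <- c(errs, de$log2_fc[isde] - tt$true_log2fc[isde])
    ## closed-form OLS standard error per analyte
    fit <- suppressWarnings(
      fit_protein_models(signal_abundance(sim), sim$metadata))
    ses <- c(ses, sqrt(fit$v_unscaled) * tt$noise_sd[isde])
  }
  ## bias bounded by the Monte-Carlo band of the pooled estimates
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
  expect_lt(abs(sd(errs) / sqrt(mean(ses^2)) - 1), 0.1)
})

test_that("moderation limits recover ordinary and fully-shrunk t-tests", {
  dat <- toy_log2()
  fit <- fit_protein_models(dat$x, dat$md)
  ## d0 = 0: moderated t equals the direct OLS t-test
  eb0 <- moderate_empirical_bayes(fit$s2, fit$df_residual, fit$effects,
                                  fit$v_unscaled, d0 = 0)
  t_ols <- fit$effects / sqrt(fit$v_unscaled * fit$s2)
  expect_lt(max(abs(eb0$t - t_ols)), 1e-10)
  p_ols <- 2 * pt(-abs(t_ols), fit$df_residual)
  expect_lt(max(abs(eb0$p - p_ols)), 1e-10)
  ## d0 = Inf: every posterior variance equals the prior
  ebi <- moderate_empirical_bayes(fit$s2, fit$df_residual, fit$effects,
                                  fit$v_unscaled, d0 = Inf)
  expect_equal(var(ebi$s2_post), 0)
  expect_error(moderate_empirical_bayes(fit$s2[1:5], 4, fit$effects[1:5],
                                        fit$v_unscaled), "fewer than 10")
})

test_that("moderated statistics agree with the limma cross-check", {
  skip_if_not_installed("limma")
  dat <- toy_log2()
  ## heterogeneous true variances so the prior df estimate is finite
  m <- unclass(dat$x)
  set.seed(33)
  m <- sweep(m, 2, runif(ncol(m), 0.5, 3), "*")
  dat$x <- af_abundance(m, "log2")
  design <- model.matrix(~ group + fetal_sex + maternal_age_years, dat$md)
  lf <- limma::eBayes(limma::lmFit(t(unclass(dat$x)), design))
  fit <- fit_protein_models(dat$x, dat$md)
  eb <- moderate_empirical_bayes(fit$s2, fit$df_residual, fit$effects,
                                 fit$v_unscaled)
  expect_equal(unname(eb$d0), unname(lf$df.prior), tolerance = 1e-6)
  expect_equal(unname(eb$s02), unname(lf$s2.prior), tolerance = 1e-6)
  expect_equal(unname(eb$t), unname(lf$t[, "groupterm"]), tolerance = 1e-8)
  expect_equal(unname(eb$p), unname(lf$p.value[, "groupterm"]),
               tolerance = 1e-8)
})

test_that("hyperparameters are recovered from their generative model", {
  set.seed(202)
  d0 <- 4; s02 <- 0.25; d <- 24
  est <- t(vapply(1:20, function(r) {
    sigma2 <- s02 * d0 / rchisq(2000, d0)
    s2 <- sigma2 * rchisq(2000, d) / d
    eb <- moderate_empirical_bayes(s2, d, rep(0, 2000), 1)
    c(eb$d0, eb$s02)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) / d0 - 1), 0.15)
  expect_lt(abs(mean(est[, 2]) / s02 - 1), 0.15)
})

test_that("BH adjustment matches the hand-worked step-up and controls nulls", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  ## monotone and order-preserving
  set.seed(7)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  ## uniform nulls yield almost no q < 0.1 discoveries
  frac <- mean(vapply(1:100, function(i)
    mean(bh_adjust(runif(1310)) < 0.1), numeric(1)))
  expect_lt(frac, 0.005)
})

test_that("the calling rule applies strict q and inclusive fold thresholds", {
  de <- data.frame(analyte_id = c("a", "b", "c"),
                   log2_fc = c(0.58, -0.60, log2(1.5)),
                   fold_change = 2^abs(c(0.58, -0.60, log2(1.5))),
                   q = c(0.01, 0.05, 0.1))
  out <- call_significant(de, fc_min = 1.5, q_de = 0.1)
  expect_equal(out$table$significant, c(FALSE, TRUE, FALSE))
  expect_equal(out$table$direction, c("up", "down", "up"))
  expect_equal(out$n_down, 1)
})

test_that("called analytes are overwhelmingly true and correctly signed", {
  precision <- dir_agree <- c()
  for (s in 1:6) {
    sim <- simulate_cohort(sim_config(seed = s))
    de <- run_differential_abundance(signal_abundance(sim), sim$metadata,
                                     sim$annotation)
    tt <- truth_of(sim, de)
    called <- de$significant
    precision <- c(precision, mean(tt$true_log2fc[called] != 0))
    hit <- called & tt$is_de
    dir_agree <- c(dir_agree, mean(sign(de$log2_fc[hit]) ==
                                     sign(tt$true_log2fc[hit])))
  }
  expect_gte(mean(precision), 0.95)
  expect_gte(mean(dir_agree), 0.99)
})

test_that("group-label swap negates fold changes and keeps p-values", {
  sim <- simulate_cohort(small_config(seed = 13))
  de <- run_differential_abundance(signal_abundance(sim), sim$metadata,
                                   sim$annotation)
  md2 <- sim$metadata
  md2$group <- factor(md2$group, levels = c("term", "midtrimester"))
  fit2 <- suppressWarnings(fit_protein_models(signal_abundance(sim), md2))
  keep <- !sim$annotation$is_control
  fit2$effects <- fit2$effects[sim$annotation$analyte_id[keep]]
  expect_equal(unname(fit2$effects), -de$log2_fc, tolerance = 1e-10)
  eb2 <- moderate_empirical_bayes(fit2$s2[sim$annotation$analyte_id[keep]],
                                  fit2$df_residual, fit2$effects,
                                  fit2$v_unscaled)
  expect_equal(unname(eb2$p), de$p, tolerance = 1e-10)
})

test_that("a weak BMI covariate barely moves the fold changes", {
  rs <- agree <- c()
  for (s in 1:3) {
    sim <- simulate_cohort(sim_config(seed = s))
    x <- signal_abundance(sim)
    deA <- run_differential_abundance(x, sim$metadata, sim$annotation)
    deB <- run_differential_abundance(x, sim$metadata, sim$annotation,
                                      covariates = c("fetal_sex",
                                                     "maternal_age_years",
                                                     "bmi_kg_m2"))
    cmp <- compare_adjustments(deA, deB)
    rs <- c(rs, cmp$r); agree <- c(agree, cmp$direction_agreement)
  }
  expect_gt(min(rs), 0.99)
  expect_gte(mean(agree), 0.999)
})

test_that("the midtrimester split respects the printed phase boundaries", {
  md <- data.frame(sample_id = c("a", "b", "c", "d"),
                   group = "midtrimester",
                   gestational_age_weeks = c(16.4, 21.0, 21.1, 24.0))
  sp <- split_midtrimester(md)
  expect_equal(sp$early, c("a", "b"))  # 21.0 weeks is still early
  expect_equal(sp$late, c("c", "d"))   # 21.1 weeks is late
  expect_error(split_midtrimester(md[1:2, ]), "empty late")
  md$group <- "term"
  expect_error(split_midtrimester(md), "midtrimester samples only")
})

test_that("the late-vs-early contrast runs end to end", {
  sim <- simulate_cohort(small_config(seed = 14))
  de <- run_differential_abundance(signal_abundance(sim), sim$metadata,
                                   sim$annotation,
                                   contrast = "late_vs_early")
  expect_equal(attr(de, "contrast"), "late_vs_early")
  expect_equal(nrow(de), sum(!sim$annotation$is_control))
  expect_true(all(de$q >= de$p - 1e-15))
})
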