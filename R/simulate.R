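#' Synthetic cohort configuration
#'
#' Parameters of the ground-truth generator. Defaults emulate the study
#' design the pipeline targets: 15 midtrimester (16.4-24.0 weeks) and 13
#' term (37.0-41.0 weeks) amniotic fluid samples assayed on a 1310-analyte
#' aptamer panel, with a quarter of analytes carrying a true group effect
#' whose magnitude always exceeds the 1.5-fold calling threshold,
#' per-analyte noise variances drawn from a scaled inverse chi-square
#' prior, three correlated protein modules planted among the affected
#' analytes via gestational-age-driven latent factors, tissue-specific
#' signature genes with a planted term-group shift in one tissue,
#' per-sample hybridization scale factors, three dilution bins, and two
#' assay plates with per-plate calibration biases.
#'
#' @param n_mid,n_term group sample sizes.
#' @param n_analytes total panel size, including controls.
#' @param n_controls number of noise-free spiked control analytes used by
#'   hybridization normalization.
#' @param de_fraction fraction of the panel with a true group effect.
#' @param effect_min_lfc minimum |log2 fold change| of a planted effect.
#' @param effect_rate rate of the exponential tail added above
#'   `effect_min_lfc`; planted |log2FC| = `effect_min_lfc` + Exp(rate),
#'   random sign.
#' @param var_d0,var_s02 prior degrees of freedom and prior variance of the
#'   scaled-inverse-chi-square noise variances: sd^2 = s02 * d0 / chisq(d0).
#' @param module_sizes integer vector of planted module sizes (members are
#'   drawn from the affected analytes); use `integer(0)` for no modules.
#' @param module_amplitude standard deviation of each module's latent
#'   factor on the log2 scale.
#' @param module_loading_range range of member loadings on the factor.
#' @param n_tissues,signature_size tissues in the companion atlas and
#'   signature genes planted per tissue.
#' @param tissue_shift term-group shift, in units of each analyte's noise
#'   SD, applied to the signature analytes of `shifted_tissue` (0 disables).
#' @param shifted_tissue index of the tissue receiving the shift.
#' @param sex_effect_sd,age_effect_sd,bmi_effect_sd SDs of per-analyte
#'   covariate coefficients (log2 per level / per year / per kg/m2).
#' @param hyb_sdlog,plate_sdlog log-normal spreads of the per-sample
#'   hybridization factors and per-plate-by-analyte calibration factors.
#' @param n_plates number of assay plates.
#' @param baseline_mean,baseline_sd distribution of per-analyte baseline
#'   log2 abundance.
#' @param seed RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_mid = 15L, n_term = 13L, n_analytes = 1310L,
                       n_controls = 10L, de_fraction = 0.25,
                       effect_min_lfc = log2(1.5), effect_rate = 1,
                       var_d0 = 4, var_s02 = 0.25,
                       module_sizes = c(110L, 100L, 90L),
                       module_amplitude = 0.5,
                       module_loading_range = c(0.4, 0.9),
                       n_tissues = 5L, signature_size = 10L,
                       tissue_shift = 1, shifted_tissue = 1L,
                       sex_effect_sd = 0.2, age_effect_sd = 0.02,
                       bmi_effect_sd = 0.005,
                       hyb_sdlog = 0.2, plate_sdlog = 0.1, n_plates = 2L,
                       baseline_mean = 10, baseline_sd = 1.5, seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_mid, cfg$n_term, cfg$n_analytes, cfg$n_plates,
              cfg$n_tissues, cfg$signature_size)
  if (any(counts < 1)) stop("all counts must be positive")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  if (cfg$var_d0 <= 0 || cfg$var_s02 <= 0)
    stop("variance prior requires d0 > 0 and s0^2 > 0")
  if (cfg$effect_min_lfc < 0 || cfg$effect_rate <= 0)
    stop("invalid effect-size parameters")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an aptamer proteomics cohort with planted ground truth
#'
#' Generates a raw-scale abundance matrix together with sample metadata,
#' analyte annotation, and a `truth` list recording everything that was
#' planted. The log2 signal for a non-control analyte is
#' baseline + group effect + covariate effects + module factor x loading +
#' tissue shift + Gaussian noise; raw values are `2^signal` scaled by the
#' per-sample hybridization factor and the per-plate-by-analyte
#' calibration factor. Control analytes are noise-free spiked references
#' carrying neither biological effects nor plate bias, so the planted
#' hybridization factors are exactly recoverable from them. Module latent
#' factors are smooth functions of gestational age, centered within each
#' group so that module membership adds correlation structure without a
#' group-mean effect.
#'
#' @param config a [sim_config()].
#' @return list with elements `abundance` (raw [af_abundance()]),
#'   `metadata`, `annotation` (data.frames), and `truth` (list with
#'   per-analyte and per-sample truth tables, the noise-free-of-factors
#'   `log2_signal` matrix, planted `plate_factors`, `control_reference`
#'   levels, module factor matrix, and per-tissue gene lists).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_ctl <- cfg$n_controls
  n_feat <- cfg$n_analytes - n_ctl
  if (n_feat < 1) stop("n_controls must be smaller than n_analytes")
  if (sum(cfg$module_sizes) > n_feat)
    stop("module sizes exceed the number of non-control analytes")
  set.seed(cfg$seed)

  ## --- samples ---
  n <- cfg$n_mid + cfg$n_term
  sample_id <- sprintf("S%02d", seq_len(n))
  group <- factor(rep(c("midtrimester", "term"), c(cfg$n_mid, cfg$n_term)),
                  levels = c("midtrimester", "term"))
  ga <- ifelse(group == "midtrimester",
               stats::runif(n, 16.4, 24.0), stats::runif(n, 37.0, 41.0))
  fetal_sex <- factor(sample(c("F", "M"), n, replace = TRUE),
                      levels = c("F", "M"))
  maternal_age <- round(ifelse(group == "midtrimester",
                               stats::rnorm(n, 30, 4),
                               stats::rnorm(n, 24, 3)), 1)
  maternal_age <- pmin(pmax(maternal_age, 18), 45)
  bmi <- round(pmin(pmax(ifelse(group == "midtrimester",
                                stats::rnorm(n, 28, 3),
                                stats::rnorm(n, 32, 4)), 18), 50), 1)
  plate_id <- sprintf("P%d", sample(rep_len(seq_len(cfg$n_plates), n)))
  hyb_factor <- stats::rlnorm(n, 0, cfg$hyb_sdlog)
  metadata <- data.frame(sample_id = sample_id, group = group,
                         gestational_age_weeks = round(ga, 1),
                         fetal_sex = fetal_sex,
                         maternal_age_years = maternal_age,
                         bmi_kg_m2 = bmi, plate_id = plate_id,
                         stringsAsFactors = FALSE)
  ga <- metadata$gestational_age_weeks

  ## --- analytes ---
  feat_id <- sprintf("SOMA%04d", seq_len(n_feat))
  ctl_id <- sprintf("CTRL%02d", seq_len(n_ctl))
  analyte_id <- c(feat_id, ctl_id)
  gene <- sprintf("GENE%04d", seq_len(n_feat))
  ## a small fraction of reagents target multi-chain proteins
  multi <- sample(n_feat, max(1L, round(0.01 * n_feat)))
  gene_symbols <- gene
  gene_symbols[multi] <- paste(gene[multi],
                               sprintf("GENE%04dB", multi))
  baseline <- stats::rnorm(n_feat, cfg$baseline_mean, cfg$baseline_sd)
  ctl_baseline <- stats::rnorm(n_ctl, cfg$baseline_mean, 0.5)
  noise_sd <- sqrt(cfg$var_s02 * cfg$var_d0 / stats::rchisq(n_feat, cfg$var_d0))

  ## planted group effects
  n_de <- round(cfg$de_fraction * cfg$n_analytes)
  if (n_de > n_feat) stop("de_fraction too large for the non-control panel")
  de_idx <- sort(sample(n_feat, n_de))
  de_lfc <- numeric(n_feat)
  if (n_de > 0)
    de_lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      (cfg$effect_min_lfc + stats::rexp(n_de, cfg$effect_rate))
  is_de <- seq_len(n_feat) %in% de_idx

  ## modules among affected analytes (the network stage runs on the
  ## differentially abundant set, as in the study design)
  module_id <- integer(n_feat)
  module_loading <- numeric(n_feat)
  n_mod <- length(cfg$module_sizes)
  module_factors <- NULL
  if (n_mod > 0 && n_de > 0) {
    if (sum(cfg$module_sizes) > n_de)
      stop("module sizes exceed the number of planted affected analytes")
    pool <- sample(de_idx)
    off <- 0L
    g_std <- as.numeric(scale(ga))
    ## three gestational-age trajectory shapes, mutually near-orthogonal
    ## within groups: U-shaped (quadratic component orthogonal to the
    ## group contrast and the linear trend), decreasing, increasing
    quad <- stats::resid(stats::lm(g_std^2 ~ group + g_std))
    shapes <- vapply(seq_len(n_mod), function(m) {
      switch(1L + (m - 1L) %% 3L, quad, -g_std, g_std)
    }, numeric(n))
    ## effect direction coherent with the module trajectory, as observed
    ## for gestational-age modules (decreasing modules are down at term)
    shape_sign <- rep_len(c(-1, -1, 1), n_mod)
    module_factors <- matrix(0, n, n_mod,
                             dimnames = list(sample_id,
                                             paste0("M", seq_len(n_mod))))
    for (m in seq_len(n_mod)) {
      idx <- pool[(off + 1L):(off + cfg$module_sizes[m])]
      off <- off + cfg$module_sizes[m]
      module_id[idx] <- m
      module_loading[idx] <- stats::runif(length(idx),
                                          cfg$module_loading_range[1],
                                          cfg$module_loading_range[2])
      de_lfc[idx] <- shape_sign[m] * abs(de_lfc[idx])
      f <- shapes[, m] + stats::rnorm(n, 0, 0.4)
      ## remove group means so module factors carry no group contrast
      f <- f - stats::ave(f, group)
      module_factors[, m] <- cfg$module_amplitude * f / stats::sd(f)
    }
  }

  ## tissue-specific signature analytes among unaffected analytes
  tissue_id <- integer(n_feat)
  tissue_lfc <- numeric(n_feat)
  free <- setdiff(which(!is_de), multi)
  need <- cfg$n_tissues * cfg$signature_size
  if (need > length(free))
    stop("tissue signature sizes exceed available unaffected analytes")
  tpick <- sample(free, need)
  tissue_id[tpick] <- rep(seq_len(cfg$n_tissues), each = cfg$signature_size)
  if (cfg$tissue_shift != 0) {
    sh <- tissue_id == cfg$shifted_tissue
    tissue_lfc[sh] <- cfg$tissue_shift * noise_sd[sh]
  }
  true_log2fc <- de_lfc + tissue_lfc

  ## covariate coefficients
  sex_coef <- stats::rnorm(n_feat, 0, cfg$sex_effect_sd)
  age_coef <- stats::rnorm(n_feat, 0, cfg$age_effect_sd)
  bmi_coef <- stats::rnorm(n_feat, 0, cfg$bmi_effect_sd)

  ## --- assemble the log2 signal ---
  term_ind <- as.numeric(group == "term")
  male_ind <- as.numeric(fetal_sex == "M")
  age_c <- maternal_age - mean(maternal_age)
  bmi_c <- bmi - mean(bmi)
  signal <- matrix(rep(baseline, each = n), n, n_feat) +
    outer(term_ind, true_log2fc) +
    outer(male_ind, sex_coef) +
    outer(age_c, age_coef) +
    outer(bmi_c, bmi_coef) +
    matrix(stats::rnorm(n * n_feat, 0, rep(noise_sd, each = n)), n, n_feat)
  if (!is.null(module_factors))
    signal <- signal + module_factors %*%
      t(outer(module_loading, seq_len(n_mod),
              function(l, m) l * (module_id == m)))
  ctl_signal <- matrix(rep(ctl_baseline, each = n), n, n_ctl)
  signal <- cbind(signal, ctl_signal)
  dimnames(signal) <- list(sample_id, analyte_id)

  ## --- apply assay-scale factors ---
  plate_levels <- sort(unique(plate_id))
  plate_factors <- matrix(stats::rlnorm(length(plate_levels) * n_feat,
                                        0, cfg$plate_sdlog),
                          length(plate_levels), n_feat,
                          dimnames = list(plate_levels, feat_id))
  plate_factors <- cbind(plate_factors,
                         matrix(1, length(plate_levels), n_ctl,
                                dimnames = list(plate_levels, ctl_id)))
  raw <- 2^signal * hyb_factor *
    plate_factors[match(plate_id, plate_levels), , drop = FALSE]
  abundance <- af_abundance(raw, scale = "raw")

  dilution_bin <- as.integer(cut(baseline, stats::quantile(
    baseline, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE))
  annotation <- data.frame(
    analyte_id = analyte_id,
    gene_symbols = c(gene_symbols, rep("", n_ctl)),
    protein_name = c(paste("Protein", gene), paste("Spike control", ctl_id)),
    dilution_bin = c(dilution_bin, rep(NA_integer_, n_ctl)),
    is_control = rep(c(FALSE, TRUE), c(n_feat, n_ctl)),
    stringsAsFactors = FALSE)

  truth_analytes <- data.frame(
    analyte_id = analyte_id,
    is_control = annotation$is_control,
    noise_sd = c(noise_sd, rep(0, n_ctl)),
    is_de = c(is_de, rep(FALSE, n_ctl)),
    de_lfc = c(de_lfc, rep(0, n_ctl)),
    tissue_id = c(tissue_id, rep(0L, n_ctl)),
    tissue_lfc = c(tissue_lfc, rep(0, n_ctl)),
    true_log2fc = c(true_log2fc, rep(0, n_ctl)),
    module_id = c(module_id, rep(0L, n_ctl)),
    module_loading = c(module_loading, rep(0, n_ctl)),
    sex_coef = c(sex_coef, rep(0, n_ctl)),
    age_coef = c(age_coef, rep(0, n_ctl)),
    bmi_coef = c(bmi_coef, rep(0, n_ctl)),
    baseline = c(baseline, ctl_baseline),
    stringsAsFactors = FALSE)
  truth_samples <- cbind(metadata,
                         data.frame(hyb_factor = hyb_factor,
                                    stringsAsFactors = FALSE))
  tissue_genes <- lapply(seq_len(cfg$n_tissues), function(t)
    sort(gene[tissue_id == t]))
  names(tissue_genes) <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))

  list(abundance = abundance,
       metadata = metadata,
       annotation = annotation,
       truth = list(analytes = truth_analytes, samples = truth_samples,
                    log2_signal = signal, plate_factors = plate_factors,
                    control_reference = stats::setNames(2^ctl_baseline, ctl_id),
                    module_factors = module_factors,
                    tissue_genes = tissue_genes,
                    config = cfg))
}

#' Simulate a gene-by-tissue expression atlas with planted signatures
#'
#' Builds an atlas consistent with a simulated cohort: the signature genes
#' recorded in `truth` receive own-tissue expression 40-80x the median of
#' the remaining tissues (comfortably above the 30x specificity rule),
#' while all other genes stay below a 2x ratio by construction. Extra
#' genes absent from the assay panel are added so that panel intersection
#' is exercised.
#'
#' @param config the [sim_config()] used for the cohort.
#' @param truth the `truth` element returned by [simulate_cohort()].
#' @param n_extra_genes off-panel genes appended to the atlas.
#' @return list with `atlas` (genes x tissues matrix) and `signatures`
#'   (per-tissue planted gene vectors).
#' @export
simulate_tissue_atlas <- function(config, truth, n_extra_genes = 50L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tissues < 2) stop("atlas requires at least 2 tissues")
  set.seed(config$seed + 1000L)
  panel <- truth$analytes[!truth$analytes$is_control, ]
  ## primary mapped symbol of each panel analyte plus off-panel genes
  genes <- sub("SOMA", "GENE", panel$analyte_id)
  genes <- unique(c(genes, sprintf("OFFPANEL%03d", seq_len(n_extra_genes))))
  tissues <- names(truth$tissue_genes)
  m <- matrix(stats::runif(length(genes) * length(tissues), 5, 10),
              length(genes), length(tissues),
              dimnames = list(genes, tissues))
  for (t in seq_along(tissues)) {
    sig <- truth$tissue_genes[[t]]
    if (!length(sig)) next
    other_med <- apply(m[sig, -t, drop = FALSE], 1, stats::median)
    m[sig, t] <- other_med * stats::runif(length(sig), 40, 80)
  }
  list(atlas = m, signatures = truth$tissue_genes)
}

#' Simulate a prior-study differential table with controlled concordance
#'
#' Produces an external differential-abundance table (gene, log2 fold
#' change, significance flag) whose fold changes are a
#' correlation-controlled mixture of the cohort's true effects and
#' independent noise: `prior = corr_target * t + sqrt(1 - corr_target^2) *
#' sd(t) * z`. With `corr_target = 1` the prior equals the truth exactly.
#'
#' @param truth the `truth` element of [simulate_cohort()].
#' @param corr_target Pearson correlation between prior and true log2 fold
#'   changes, in `[-1, 1]`.
#' @param sig_fraction fraction of prior genes flagged significant.
#' @param seed RNG seed.
#' @param de_only restrict the table to analytes with a planted effect.
#' @return data.frame with `gene`, `log2_fc`, `significant`.
#' @export
simulate_prior_study <- function(truth, corr_target, sig_fraction = 0.6,
                                 seed = 1L, de_only = FALSE) {
  if (abs(corr_target) > 1) stop("corr_target must be in [-1, 1]")
  an <- truth$analytes[!truth$analytes$is_control, ]
  if (de_only) an <- an[an$is_de, ]
  if (!nrow(an)) stop("empty truth table")
  set.seed(seed)
  t <- an$true_log2fc
  s <- stats::sd(t)
  if (!is.finite(s) || s == 0) s <- 1
  z <- stats::rnorm(length(t))
  prior <- corr_target * t + sqrt(1 - corr_target^2) * s * z
  data.frame(gene = sub("SOMA", "GENE", an$analyte_id),
             log2_fc = prior,
             significant = stats::runif(length(t)) < sig_fraction,
             stringsAsFactors = FALSE)
}
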