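#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order — normalize, cohort, differential
#' abundance (both contrasts), PCA, network modules, enrichment, tissue
#' signatures, concordance — writing each stage's table(s) to `outdir`
#' along with a run manifest (configuration, seed, versions). Stages can
#' be skipped; later stages use whatever prerequisites are available and
#' error, naming the stage, when one is missing.
#'
#' @param inputs list with elements `abundance` (raw or log2
#'   [af_abundance()]), `metadata`, `annotation`, and optionally
#'   `gene_sets` (list from [read_gene_sets()]), `atlas` (matrix), and
#'   `prior` (data.frame).
#' @param config an [af_config()].
#' @param outdir output directory (created if absent).
#' @param stages subset of `c("normalize", "cohort", "de", "pca",
#'   "modules", "enrich", "tissues", "concord")`.
#' @param covariates covariate columns for the differential models.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(inputs, config = af_config(), outdir,
                         stages = c("normalize", "cohort", "de", "pca",
                                    "modules", "enrich", "tissues",
                                    "concord"),
                         covariates = c("fetal_sex",
                                        "maternal_age_years")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)
  res <- list()
  md <- validate_metadata(inputs$metadata, strict = config$strict_metadata)
  an <- validate_annotation(inputs$annotation)
  x <- inputs$abundance
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("normalize" %in% stages && abundance_scale(x) == "raw") {
    nc <- stage("normalize", {
      nc <- normalize_chain(x, an, md)
      write_matrix_tsv(unclass(nc$abundance),
                       file.path(outdir, "log2_abundance.tsv"))
      write_matrix_tsv(rbind(hybridization = nc$factors$hybridization),
                       file.path(outdir, "hybridization_factors.tsv"),
                       id_name = "factor")
      nc
    })
    res$normalization <- nc
    x <- nc$abundance
  } else if (abundance_scale(x) == "raw") {
    x <- log2_transform(x)
  }

  if ("cohort" %in% stages) {
    res$cohort <- stage("cohort", {
      vars <- data.frame(
        name = c("gestational_age_weeks", "maternal_age_years",
                 "bmi_kg_m2", "fetal_sex"),
        type = c("continuous", "continuous", "continuous", "binary"),
        positive = c(NA, NA, NA, "F"), stringsAsFactors = FALSE)
      vars <- vars[vars$name %in% names(md), , drop = FALSE]
      s <- summarize_cohort(md, vars)
      write_table_tsv(s, file.path(outdir, "cohort_summary.tsv"))
      s
    })
  }

  if ("de" %in% stages) {
    res$de_term <- stage("de", {
      de <- run_differential_abundance(x, md, an, covariates = covariates,
                                       contrast = "term_vs_mid",
                                       config = config)
      write_table_tsv(de, file.path(outdir, "de_term_vs_mid.tsv"))
      de
    })
    res$de_mid <- stage("de", {
      de <- run_differential_abundance(x, md, an, covariates =
                                         setdiff(covariates, "group"),
                                       contrast = "late_vs_early",
                                       config = config)
      write_table_tsv(de, file.path(outdir, "de_late_vs_early.tsv"))
      de
    })
  }

  if ("pca" %in% stages) {
    res$pca <- stage("pca", {
      keep <- an$analyte_id[!an$is_control]
      pca <- compute_pca(unclass(x)[, intersect(analyte_ids(x), keep),
                                    drop = FALSE])
      ga <- md$gestational_age_weeks[match(rownames(pca$scores),
                                           md$sample_id)]
      trait <- pc_trait_correlation(pca$scores[, 1], ga)
      write_matrix_tsv(pca$scores, file.path(outdir, "pca_scores.tsv"))
      write_table_tsv(
        data.frame(component = seq_along(pca$variance_fraction),
                   variance_fraction = pca$variance_fraction),
        file.path(outdir, "pca_variance.tsv"))
      list(pca = pca, trait = trait)
    })
  }

  if ("modules" %in% stages) {
    res$modules <- stage("modules", {
      if (is.null(res$de_term) || is.null(res$de_mid))
        stop("requires the 'de' stage")
      union_ids <- union(res$de_term$analyte_id[res$de_term$significant],
                         res$de_mid$analyte_id[res$de_mid$significant])
      if (length(union_ids) < config$min_module_size)
        stop("too few differentially abundant analytes for networks")
      nm <- run_network_modules(x, union_ids, config = config)
      write_table_tsv(nm$assignment, file.path(outdir, "modules.tsv"))
      if (!is.null(nm$hubs)) {
        write_table_tsv(nm$hubs, file.path(outdir, "module_hubs.tsv"))
        write_matrix_tsv(nm$eigen$eigenprofiles,
                         file.path(outdir, "module_eigenprofiles.tsv"))
        ga <- md$gestational_age_weeks[match(rownames(nm$eigen$eigenprofiles),
                                             md$sample_id)]
        curves <- do.call(rbind, lapply(
          colnames(nm$eigen$eigenprofiles), function(m) {
            lp <- loess_profile(ga, nm$eigen$eigenprofiles[, m],
                                span = config$loess_span)
            lp$module <- m
            lp
          }))
        write_table_tsv(curves, file.path(outdir, "module_loess.tsv"))
      }
      nm
    })
  }

  if ("enrich" %in% stages) {
    res$enrichment <- stage("enrich", {
      if (is.null(inputs$gene_sets)) stop("requires 'gene_sets' input")
      if (is.null(res$de_term)) stop("requires the 'de' stage")
      universe <- map_analytes_to_genes(an, an$analyte_id[!an$is_control])
      up <- res$de_term$analyte_id[res$de_term$significant &
                                     res$de_term$direction == "up"]
      dn <- res$de_term$analyte_id[res$de_term$significant &
                                     res$de_term$direction == "down"]
      enr <- list(
        up = hypergeometric_enrichment(map_analytes_to_genes(an, up),
                                       universe, inputs$gene_sets,
                                       config$min_term_hits,
                                       config$q_enrich),
        down = hypergeometric_enrichment(map_analytes_to_genes(an, dn),
                                         universe, inputs$gene_sets,
                                         config$min_term_hits,
                                         config$q_enrich))
      write_table_tsv(enr$up, file.path(outdir, "enrichment_up.tsv"))
      write_table_tsv(enr$down, file.path(outdir, "enrichment_down.tsv"))
      enr
    })
  }

  if ("tissues" %in% stages) {
    res$tissues <- stage("tissues", {
      if (is.null(inputs$atlas)) stop("requires 'atlas' input")
      panel <- map_analytes_to_genes(an, an$analyte_id[!an$is_control])
      sigs <- build_tissue_signatures(inputs$atlas, panel,
                                      config$specificity_ratio,
                                      config$signature_top_n)
      scores <- score_tissue_signatures(x, sigs, an, md)
      cmp <- compare_tissue_scores(scores, md, config$q_tissue)
      write_matrix_tsv(scores, file.path(outdir, "tissue_scores.tsv"))
      write_table_tsv(cmp, file.path(outdir, "tissue_comparison.tsv"))
      list(signatures = sigs, scores = scores, comparison = cmp)
    })
  }

  if ("concord" %in% stages) {
    res$concordance <- stage("concord", {
      if (is.null(inputs$prior)) stop("requires 'prior' input")
      if (is.null(res$de_term)) stop("requires the 'de' stage")
      pairs <- harmonize_ids(res$de_term, an, inputs$prior)
      cc <- concordance(pairs)
      write_table_tsv(cc$pairs, file.path(outdir, "concordance_pairs.tsv"))
      write_table_tsv(
        data.frame(n_common = cc$n_common, rho = cc$rho, p = cc$p,
                   same_direction_n = cc$same_direction_n,
                   same_direction_fraction = cc$same_direction_fraction),
        file.path(outdir, "concordance.tsv"))
      cc
    })
  }

  manifest <- list(
    package = "afproteo",
    version = as.character(utils::packageVersion("afproteo")),
    r_version = R.version.string,
    seed = config$rng_seed,
    stages = stages,
    covariates = covariates,
    config = unclass(config))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
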