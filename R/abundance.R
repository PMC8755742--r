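#' Abundance matrix container
#'
#' An `af_abundance` object is the central data structure of the pipeline: a
#' numeric samples-by-analytes matrix of aptamer readouts (relative
#' fluorescence units, RFU) carrying a scale flag that records whether the
#' values are raw RFU or log2(RFU). Samples are always stored in rows;
#' readers transpose on ingest when the file has samples in columns.
#'
#' @param values numeric matrix, samples in rows, analytes in columns, with
#'   complete dimnames.
#' @param scale `"raw"` (strictly positive RFU) or `"log2"`.
#' @return an object of class `af_abundance`: the matrix with a `scale`
#'   attribute.
#' @examples
#' m <- matrix(2^rnorm(6, 10), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
#' ab <- af_abundance(m, scale = "raw")
#' abundance_scale(ab)
#' @export
af_abundance <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix requires sample (row) and analyte (column) names")
  obj <- structure(values, scale = scale,
                   class = c("af_abundance", "matrix", "array"))
  validate_abundance(obj)
  obj
}

#' @rdname af_abundance
#' @param x an `af_abundance` object.
#' @export
abundance_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("object carries no abundance scale flag")
  s
}

#' @rdname af_abundance
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname af_abundance
#' @export
analyte_ids <- function(x) colnames(x)

validate_abundance <- function(x) {
  if (anyDuplicated(rownames(x))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(x))) stop("duplicate analyte ids")
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(unclass(x)), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite abundance value at sample '%s', analyte '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  if (identical(attr(x, "scale"), "raw") && any(x <= 0)) {
    bad <- which(unclass(x) <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("nonpositive raw RFU at sample '%s', analyte '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  invisible(x)
}

#' @export
print.af_abundance <- function(x, ...) {
  cat(sprintf("af_abundance: %d samples x %d analytes [%s scale]\n",
              nrow(x), ncol(x), abundance_scale(x)))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' Checks the per-sample clinical covariate table: unique sample ids, a
#' two-level `group` factor (`midtrimester`, `term`) and, under strict
#' validation, gestational ages within the sampling windows of the study
#' design (16-24 weeks for midtrimester, 37-42 weeks at term).
#'
#' @param metadata data.frame with columns `sample_id`, `group`,
#'   `gestational_age_weeks`, `fetal_sex`, `maternal_age_years`, and
#'   optionally `bmi_kg_m2` and `plate_id`.
#' @param strict enforce the per-group gestational-age windows.
#' @return the metadata, invisibly, with `group` and `fetal_sex` as factors.
#' @export
validate_metadata <- function(metadata, strict = TRUE) {
  req <- c("sample_id", "group", "gestational_age_weeks", "fetal_sex",
           "maternal_age_years")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample ids in metadata")
  metadata$group <- factor(as.character(metadata$group),
                           levels = c("midtrimester", "term"))
  if (anyNA(metadata$group)) stop("group must be 'midtrimester' or 'term'")
  metadata$fetal_sex <- factor(as.character(metadata$fetal_sex),
                               levels = c("F", "M"))
  if (anyNA(metadata$fetal_sex)) stop("fetal_sex must be 'F' or 'M'")
  if (strict) {
    ga <- metadata$gestational_age_weeks
    mid <- metadata$group == "midtrimester"
    if (any(ga[mid] < 16 | ga[mid] > 24))
      stop("midtrimester gestational age outside [16, 24] weeks")
    if (any(ga[!mid] < 37 | ga[!mid] > 42))
      stop("term gestational age outside [37, 42] weeks")
  }
  invisible(metadata)
}

#' Validate an analyte annotation table
#'
#' The annotation maps each aptamer reagent to its gene symbol(s) (one
#' reagent may target a multi-chain protein, e.g. "CGA LHB"), a protein
#' name, a serial-dilution bin, and a control flag. Every non-control
#' analyte must carry a dilution bin.
#'
#' @param annotation data.frame with columns `analyte_id`, `gene_symbols`
#'   (whitespace-separated symbols), `protein_name`, `dilution_bin`,
#'   `is_control`.
#' @return the annotation, invisibly.
#' @export
validate_annotation <- function(annotation) {
  req <- c("analyte_id", "gene_symbols", "dilution_bin", "is_control")
  miss <- setdiff(req, names(annotation))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$analyte_id)) stop("duplicate analyte ids")
  nc <- !annotation$is_control
  if (any(is.na(annotation$dilution_bin[nc])))
    stop("dilution_bin undefined for a non-control analyte")
  invisible(annotation)
}

# split "CGA LHB" -> c("CGA","LHB"), upper-cased
split_symbols <- function(x) {
  lapply(strsplit(toupper(as.character(x)), "[ ;,]+"),
         function(s) unique(s[nzchar(s)]))
}
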