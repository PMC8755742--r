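#' Hybridization normalization
#'
#' Per-sample scale correction against spiked control reagents: each
#' sample's factor is the median over controls of
#' (reference level / observed level), and every analyte in the sample is
#' multiplied by it. After normalization the per-sample median control
#' ratio is 1. This is a transparent median-ratio emulation of the
#' platform's per-sample hybridization standardization.
#'
#' @param x raw-scale [af_abundance()].
#' @param control_ids analyte ids of the hybridization controls.
#' @param reference named numeric vector of reference control levels
#'   (raw scale); defaults to each control's across-sample median.
#' @return list with `abundance` (normalized, raw scale) and `factors`
#'   (named per-sample vector).
#' @export
hybridization_normalize <- function(x, control_ids, reference = NULL) {
  check_raw(x)
  control_ids <- intersect(control_ids, analyte_ids(x))
  if (!length(control_ids)) stop("no control analytes present in the matrix")
  ctl <- unclass(x)[, control_ids, drop = FALSE]
  if (any(ctl <= 0)) stop("nonpositive control value")
  if (is.null(reference))
    reference <- apply(ctl, 2, stats::median)
  reference <- reference[control_ids]
  if (anyNA(reference) || any(reference <= 0))
    stop("reference control levels must be positive and cover all controls")
  factors <- apply(sweep(ctl, 2, reference, function(v, r) r / v), 1,
                   stats::median)
  out <- unclass(x) * factors
  list(abundance = af_abundance(out, scale = "raw"),
       factors = factors)
}

#' Median normalization within dilution bins
#'
#' Per sample and dilution bin, the factor is the median over the bin's
#' analytes of (analyte's across-sample median / analyte's value in this
#' sample); bin members in that sample are multiplied by it. With
#' `global = TRUE` all analytes form a single bin.
#'
#' @param x raw-scale [af_abundance()].
#' @param dilution_bins vector of bin labels named by (or ordered as) the
#'   analytes of `x`.
#' @param global ignore the bins and normalize against all analytes.
#' @return list with `abundance` and `factors` (samples x bins matrix).
#' @export
median_normalize <- function(x, dilution_bins, global = FALSE) {
  check_raw(x)
  v <- unclass(x)
  if (!is.null(names(dilution_bins)))
    dilution_bins <- dilution_bins[analyte_ids(x)]
  if (length(dilution_bins) != ncol(v))
    stop("dilution_bins must cover every analyte")
  if (anyNA(dilution_bins)) stop("analyte without a dilution bin")
  if (global) dilution_bins <- rep("all", ncol(v))
  bins <- split(seq_len(ncol(v)), dilution_bins)
  if (any(!lengths(bins))) stop("dilution bin with zero analytes")
  med_a <- apply(v, 2, stats::median)
  factors <- matrix(NA_real_, nrow(v), length(bins),
                    dimnames = list(rownames(v), names(bins)))
  for (b in seq_along(bins)) {
    idx <- bins[[b]]
    ratio <- sweep(1 / v[, idx, drop = FALSE], 2, med_a[idx], "*")
    f <- apply(ratio, 1, stats::median)
    factors[, b] <- f
    v[, idx] <- v[, idx, drop = FALSE] * f
  }
  list(abundance = af_abundance(v, scale = "raw"), factors = factors)
}

#' Plate calibration normalization
#'
#' Per plate and analyte, the factor is reference / (median of the analyte
#' over the plate's calibrator samples); all samples on the plate are
#' multiplied by it. When no calibrator samples are designated, every
#' sample on the plate serves as a calibrator; when no reference is given,
#' the across-plate (all-sample) median of each analyte is used.
#'
#' @param x raw-scale [af_abundance()].
#' @param plate_ids plate label per sample (named by or ordered as samples).
#' @param reference optional reference levels: a per-analyte vector, or a
#'   plates x analytes matrix of calibrator-derived expected levels.
#' @param calibrators optional list: plate label -> calibrator sample ids.
#' @return list with `abundance` and `factors` (plates x analytes matrix).
#' @export
plate_calibrate <- function(x, plate_ids, reference = NULL,
                            calibrators = NULL) {
  check_raw(x)
  v <- unclass(x)
  if (!is.null(names(plate_ids))) plate_ids <- plate_ids[sample_ids(x)]
  if (length(plate_ids) != nrow(v)) stop("plate_ids must cover every sample")
  if (anyNA(plate_ids)) stop("sample without a plate id")
  plates <- split(seq_len(nrow(v)), as.character(plate_ids))
  if (any(!lengths(plates))) stop("plate with no samples")
  if (is.null(reference)) reference <- apply(v, 2, stats::median)
  per_plate_ref <- is.matrix(reference)
  if (per_plate_ref) {
    reference <- reference[names(plates), analyte_ids(x), drop = FALSE]
  } else {
    reference <- reference[analyte_ids(x)]
  }
  if (anyNA(reference) || any(reference <= 0))
    stop("reference must be positive for every analyte")
  factors <- matrix(NA_real_, length(plates), ncol(v),
                    dimnames = list(names(plates), colnames(v)))
  for (p in names(plates)) {
    idx <- plates[[p]]
    cal <- idx
    if (!is.null(calibrators) && !is.null(calibrators[[p]])) {
      cal <- match(calibrators[[p]], rownames(v))
      if (anyNA(cal)) stop("unknown calibrator sample on plate ", p)
    }
    med <- apply(v[cal, , drop = FALSE], 2, stats::median)
    ref_p <- if (per_plate_ref) reference[p, ] else reference
    f <- ref_p / med
    factors[p, ] <- f
    v[idx, ] <- sweep(v[idx, , drop = FALSE], 2, f, "*")
  }
  list(abundance = af_abundance(v, scale = "raw"), factors = factors)
}

#' Log2 transform a raw abundance matrix
#'
#' @param x raw-scale [af_abundance()] with strictly positive values.
#' @return [af_abundance()] on the log2 scale.
#' @export
log2_transform <- function(x) {
  check_raw(x)
  if (any(unclass(x) <= 0)) stop("nonpositive value; cannot log2 transform")
  af_abundance(log2(unclass(x)), scale = "log2")
}

check_raw <- function(x) {
  if (!inherits(x, "af_abundance")) stop("expected an af_abundance object")
  if (abundance_scale(x) != "raw")
    stop("operation requires a raw-scale matrix (already log2?)")
  invisible(x)
}

#' Run the full normalization chain
#'
#' Applies hybridization, median, and plate normalization (each optional)
#' followed by the log2 transform, returning the normalized matrix and an
#' audit trail of all factors.
#'
#' @param x raw-scale [af_abundance()].
#' @param annotation analyte annotation (for control ids and dilution bins).
#' @param metadata sample metadata (for plate ids).
#' @param steps subset of `c("hyb", "median", "plate")`.
#' @param log2 apply the final log2 transform.
#' @param control_reference,plate_reference optional reference levels
#'   passed through to the individual steps.
#' @return list with `abundance` and `factors` (list per step).
#' @export
normalize_chain <- function(x, annotation, metadata,
                            steps = c("hyb", "median", "plate"),
                            log2 = TRUE, control_reference = NULL,
                            plate_reference = NULL) {
  factors <- list()
  if ("hyb" %in% steps) {
    ctl <- annotation$analyte_id[annotation$is_control]
    h <- hybridization_normalize(x, ctl, control_reference)
    x <- h$abundance; factors$hybridization <- h$factors
  }
  if ("median" %in% steps) {
    keep <- !annotation$is_control
    bins <- stats::setNames(annotation$dilution_bin, annotation$analyte_id)
    bins[annotation$analyte_id[annotation$is_control]] <- 0L
    m <- median_normalize(x, bins)
    x <- m$abundance; factors$median <- m$factors
  }
  if ("plate" %in% steps) {
    if (is.null(metadata$plate_id)) stop("metadata lacks plate_id")
    p <- plate_calibrate(x, stats::setNames(metadata$plate_id,
                                            metadata$sample_id),
                         reference = plate_reference)
    x <- p$abundance; factors$plate <- p$factors
  }
  if (log2) x <- log2_transform(x)
  list(abundance = x, factors = factors)
}
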