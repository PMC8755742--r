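#' Read an abundance matrix from delimited text
#'
#' Reads a TSV/CSV matrix with one header row and one id column. The
#' `orientation` argument declares whether samples are in rows or columns;
#' the matrix is transposed to the internal samples-in-rows convention.
#' Missing or non-numeric cells are rejected with the offending row and
#' column named, as downstream computations assume a complete matrix.
#'
#' @param path file path; a `.csv` extension implies comma separation,
#'   anything else tab.
#' @param orientation `"samples_rows"` or `"samples_cols"`.
#' @param scale `"raw"` or `"log2"` (see [af_abundance()]).
#' @return an [af_abundance()] object, samples in rows.
#' @export
read_abundance_matrix <- function(path,
                                  orientation = c("samples_rows",
                                                  "samples_cols"),
                                  scale = c("raw", "log2")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, row.names = 1,
                          colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 1) stop("matrix file has no data columns: ", path)
  m <- as.matrix(df)
  num <- suppressWarnings(array(as.numeric(m), dim(m), dimnames(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at row '%s', column '%s' in %s",
                 rownames(num)[bad[1]], colnames(num)[bad[2]], path))
  }
  if (orientation == "samples_cols") num <- t(num)
  af_abundance(num, scale = scale)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Write an abundance matrix (or any named numeric matrix) as TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces doubles exactly.
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @param id_name header for the id column.
#' @export
write_matrix_tsv <- function(x, path, id_name = "sample_id") {
  fmt <- vapply(seq_len(nrow(x)), function(i)
    paste(sprintf("%.17g", x[i, ]), collapse = "\t"), character(1))
  lines <- c(paste(c(id_name, colnames(x)), collapse = "\t"),
             paste(rownames(x), fmt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One tab-separated line per set: name, description, then gene symbols.
#' Duplicate genes within a set are collapsed; lines with fewer than three
#' fields (i.e. empty gene lists) are rejected.
#'
#' @param path GMT file path.
#' @return named list of sets; each element has `name` and `genes`
#'   (upper-cased, de-duplicated).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields (no genes)", i))
    id <- f[[1]]
    sets[[id]] <- list(name = f[[2]], genes = unique(toupper(f[-(1:2)])))
  }
  if (anyDuplicated(names(sets))) stop("duplicate term ids in GMT")
  sets
}

#' Read a gene-by-tissue expression atlas
#'
#' Expects genes in rows and tissues in columns, nonnegative median
#' expression values. Gene symbols are upper-cased; duplicated gene rows
#' are collapsed by the per-tissue median.
#'
#' @param path delimited text file.
#' @return numeric matrix, genes x tissues.
#' @export
read_tissue_atlas <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop("tissue atlas has no tissue columns: ", path)
  genes <- toupper(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric value in tissue atlas")
  if (any(m < 0)) stop("negative expression value in tissue atlas")
  if (anyDuplicated(genes)) {
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i)
      apply(m[i, , drop = FALSE], 2, stats::median)))
  } else {
    rownames(m) <- genes
  }
  m
}

#' Write a data frame as TSV with full numeric precision
#' @param df data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "")
}
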