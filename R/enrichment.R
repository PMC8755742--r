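#' Map analytes to gene symbols
#'
#' Expands each analyte into its (upper-cased) gene symbols — multi-chain
#' reagents such as "CGA LHB" contribute every listed gene — and collapses
#' duplicates. Analytes absent from the annotation are skipped with a
#' warning.
#'
#' @param annotation analyte annotation table.
#' @param analytes analyte ids to map.
#' @return character vector of unique gene symbols.
#' @export
map_analytes_to_genes <- function(annotation, analytes) {
  idx <- match(analytes, annotation$analyte_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " analyte(s) missing from annotation; skipped")
    idx <- idx[!is.na(idx)]
  }
  if (!length(idx)) return(character(0))
  sort(unique(unlist(split_symbols(annotation$gene_symbols[idx]))))
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the query (e.g. genes of the
#' up-regulated proteins) contains more of the set's genes than expected
#' under uniform sampling from the universe (the genes measurable on the
#' assay panel). p is the upper hypergeometric tail P(X >= k); terms with
#' fewer than `min_term_hits` query hits are excluded before BH
#' adjustment.
#'
#' @param query gene symbols of interest (must lie in the universe).
#' @param universe background gene symbols (the panel).
#' @param gene_sets named list as returned by [read_gene_sets()].
#' @param min_term_hits minimum query hits for a term to be tested.
#' @param q_enrich FDR threshold for the `enriched` flag.
#' @return data.frame sorted by p: `term_id`, `term_name`, `universe_n`,
#'   `term_n`, `query_n`, `hits`, `expected`, `p`, `q`, `enriched`.
#' @export
hypergeometric_enrichment <- function(query, universe, gene_sets,
                                      min_term_hits = 3,
                                      q_enrich = 0.05) {
  query <- unique(toupper(query))
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  if (!all(query %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(toupper(gene_sets[[id]]$genes)), universe)
    K <- length(set)
    if (!K) return(NULL)
    k <- length(intersect(set, query))
    if (k < min_term_hits) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = gene_sets[[id]]$name,
               universe_n = N, term_n = K, query_n = n, hits = k,
               expected = n * K / N, p = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(term_id = character(0), term_name = character(0),
                      universe_n = integer(0), term_n = integer(0),
                      query_n = integer(0), hits = integer(0),
                      expected = numeric(0), p = numeric(0),
                      q = numeric(0), enriched = logical(0)))
  rows$q <- bh_adjust(rows$p)
  rows$enriched <- rows$q < q_enrich & rows$hits >= min_term_hits
  rows[order(rows$p, rows$term_id), , drop = FALSE]
}
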