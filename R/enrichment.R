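#' Read a GMT gene-set collection
#'
#' Standard GMT layout: one set per line, tab-separated -- set id,
#' description, then member symbols. Member symbols are upper-cased and
#' de-duplicated within each set.
#'
#' @param path path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   symbol vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(structure(list(sets = list(),
                          descriptions = character(0)),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], ": fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, character(1), 1L)
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- ids
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2L), ids)
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x$sets), " sets, ",
      length(unique(unlist(x$sets))), " distinct genes\n", sep = "")
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected under sampling without replacement from the universe: the
#' one-sided upper-tail probability `P(X >= k)` of the
#' hypergeometric(N, K, n) distribution, where `N` is the universe size,
#' `K` the set size within the universe, `n` the testable query size and
#' `k` the observed overlap. P-values are BH-adjusted across the sets of
#' the collection.
#'
#' The universe defaults to the union of all collection members; supply
#' a background list explicitly to override. Query genes outside the
#' universe are dropped, with the count in the `"n_dropped"` attribute.
#'
#' @param query character vector of gene symbols.
#' @param collection a [read_gmt()] result (or a named list of symbol
#'   vectors).
#' @param universe optional explicit background gene set.
#' @param alpha significance cutoff for the `significant` flag.
#' @return data frame with columns `set_id`, `description`,
#'   `overlap_count`, `set_size`, `query_size`, `universe_size`, `p_raw`,
#'   `p_adj`, `significant`, `overlap_genes`, sorted by `p_raw` (ties by
#'   set id).
#' @export
hypergeometric_enrichment <- function(query, collection, universe = NULL,
                                      alpha = 0.05) {
  if (length(query) == 0L) stop("empty query")
  if (!inherits(collection, "gene_set_collection"))
    collection <- structure(
      list(sets = lapply(collection, function(s) unique(toupper(s))),
           descriptions = stats::setNames(rep("", length(collection)),
                                          names(collection))),
      class = "gene_set_collection")
  query <- unique(toupper(query))
  if (is.null(universe))
    universe <- unique(unlist(collection$sets, use.names = FALSE))
  else
    universe <- unique(toupper(universe))
  testable <- intersect(query, universe)
  n_dropped <- length(query) - length(testable)
  if (length(testable) == 0L) stop("no testable genes")

  N <- length(universe)
  n <- length(testable)
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], universe)
    K <- length(members)
    overlap <- intersect(testable, members)
    k <- length(overlap)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id,
               description = unname(collection$descriptions[id]),
               overlap_count = k, set_size = K, query_size = n,
               universe_size = N, p_raw = p,
               overlap_genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p_raw)
  out$significant <- out$p_raw < alpha
  out <- out[order(out$p_raw, out$set_id),
             c("set_id", "description", "overlap_count", "set_size",
               "query_size", "universe_size", "p_raw", "p_adj",
               "significant", "overlap_genes")]
  rownames(out) <- NULL
  structure(out, n_dropped = n_dropped,
            class = c("enrichment_table", "data.frame"))
}
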