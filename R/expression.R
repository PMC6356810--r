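#' Two-group expression dataset
#'
#' Container for a log2-scale expression matrix (genes in rows, samples in
#' columns) with a case/control group assignment per sample. This is the
#' input to [deg_screen()].
#'
#' @param values numeric matrix of log2 expression, genes x samples, with
#'   rownames (gene symbols) and colnames (sample ids).
#' @param groups named character vector mapping every sample id to
#'   `"case"` or `"control"` (the labels `"tumor"`/`"normal"` are accepted
#'   and normalized).
#' @param dataset_id short label identifying the dataset (e.g. a GEO
#'   accession); recorded in downstream results.
#'
#' @details Gene symbols are upper-cased and must be unique after
#'   upper-casing; duplicated symbols are rejected rather than silently
#'   collapsed. Genes containing any missing or non-finite value are
#'   dropped at construction and their symbols recorded in the
#'   `"dropped_genes"` attribute. Each group must contain at least two
#'   samples.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `groups`, `dataset_id`.
#' @export
expression_dataset <- function(values, groups, dataset_id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (genes) and colnames (samples)")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  groups <- normalize_groups(groups)
  missing_grp <- setdiff(colnames(values), names(groups))
  if (length(missing_grp))
    stop("samples without a group assignment: ",
         paste(missing_grp, collapse = ", "))
  groups <- groups[colnames(values)]
  if (sum(groups == "case") < 2L || sum(groups == "control") < 2L)
    stop("need at least 2 samples per group")

  ok <- apply(values, 1L, function(x) all(is.finite(x)))
  dropped <- rownames(values)[!ok]
  values <- values[ok, , drop = FALSE]

  structure(
    list(values = values, groups = groups, dataset_id = dataset_id),
    dropped_genes = dropped,
    class = "expression_dataset"
  )
}

normalize_groups <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named vector (names = sample ids)")
  g <- tolower(as.character(groups))
  g[g %in% c("case", "tumor", "tumour", "disease")] <- "case"
  g[g %in% c("control", "normal", "healthy")] <- "control"
  bad <- setdiff(unique(g), c("case", "control"))
  if (length(bad))
    stop("unrecognized group label(s): ", paste(bad, collapse = ", "),
         " (expected case/tumor or control/normal)")
  names(g) <- names(groups)
  g
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", x$dataset_id, "\n", sep = "")
  cat("  genes:   ", nrow(x$values), "\n", sep = "")
  cat("  samples: ", ncol(x$values),
      " (", sum(x$groups == "case"), " case / ",
      sum(x$groups == "control"), " control)\n", sep = "")
  nd <- length(attr(x, "dropped_genes"))
  if (nd) cat("  dropped (non-finite values): ", nd, "\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Reads a tab-separated expression table whose first column holds gene
#' symbols and whose header row holds sample ids (the layout of a GEO
#' series-matrix table body). Values are taken to be on the log2 scale
#' unless `linear = TRUE`, in which case `log2(x + 1)` is applied.
#'
#' @param path path to the TSV file.
#' @param groups named character vector or data frame / path understood by
#'   [read_groups()].
#' @param dataset_id label for the dataset; defaults to the file name.
#' @param genes_as `"rows"` (default) if the file stores one gene per row,
#'   `"cols"` if it stores one sample per row (the table is transposed on
#'   load).
#' @param linear set `TRUE` when the file holds linear-scale intensities.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, groups, dataset_id = basename(path),
                            genes_as = c("rows", "cols"), linear = FALSE) {
  genes_as <- match.arg(genes_as)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "!")
  if (ncol(tab) < 2L) stop("expression table needs >= 2 columns")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (genes_as == "cols") m <- t(m)
  if (linear) m <- log2(m + 1)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups))
    groups <- read_groups(groups)
  expression_dataset(m, groups, dataset_id = dataset_id)
}

#' Read a sample-to-group map
#'
#' Two-column TSV: sample id, group label (case/tumor or control/normal).
#' A header row is detected and skipped when its second field is not a
#' recognized group label.
#'
#' @param path path to the TSV file.
#' @return named character vector mapping sample id to `"case"`/`"control"`.
#' @export
read_groups <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group map needs 2 columns: sample_id, group")
  lab <- tolower(as.character(tab[[2L]]))
  known <- c("case", "tumor", "tumour", "disease",
             "control", "normal", "healthy")
  if (!(lab[1L] %in% known)) tab <- tab[-1L, , drop = FALSE]
  normalize_groups(stats::setNames(as.character(tab[[2L]]),
                                   as.character(tab[[1L]])))
}
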