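#' Read a weighted edge list
#'
#' Parses a 3+ column interaction table (gene, gene, score). Two dialects
#' are understood: `"string_flat"`, the STRING flat-file layout whose
#' combined scores sit on a 0--1000 integer scale and are divided by 1000,
#' and `"generic"`, whose scores are already in (0, 1]. With
#' `dialect = "auto"` (the default) the scale is inferred: any score above
#' 1 switches the whole file to the 0--1000 convention.
#'
#' Symbols are upper-cased; self-loops are dropped, as are rows whose
#' score is not positive, with counts recorded in attributes
#' `"n_self_loops"` / `"n_nonpositive"`.
#'
#' @param path path to a whitespace- or tab-separated file; a header line
#'   is skipped when its third field is non-numeric.
#' @param dialect `"auto"`, `"string_flat"` or `"generic"`.
#' @return data frame with columns `gene_a`, `gene_b`, `score`.
#' @export
read_edge_list <- function(path, dialect = c("auto", "string_flat",
                                             "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(structure(data.frame(gene_a = character(0),
                                gene_b = character(0),
                                score = numeric(0),
                                stringsAsFactors = FALSE),
                     n_self_loops = 0L, n_nonpositive = 0L))
  fields <- strsplit(lines, "[ \t]+")
  first_line <- 1L
  if (length(fields[[1L]]) >= 3L &&
      is.na(suppressWarnings(as.numeric(fields[[1L]][3L]))))
    first_line <- 2L

  rows <- lapply(seq.int(first_line, length(fields)), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop("line ", i, ": expected >= 3 columns (gene, gene, score)")
    sc <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(sc)) stop("line ", i, ": non-numeric score '", f[3L], "'")
    list(a = toupper(f[1L]), b = toupper(f[2L]), score = sc)
  })
  a <- vapply(rows, `[[`, character(1), "a")
  b <- vapply(rows, `[[`, character(1), "b")
  score <- vapply(rows, `[[`, numeric(1), "score")

  if (dialect == "string_flat" ||
      (dialect == "auto" && any(score > 1)))
    score <- score / 1000

  nonpos <- score <= 0
  self <- a == b & !nonpos
  keep <- !nonpos & !self
  structure(
    data.frame(gene_a = a[keep], gene_b = b[keep], score = score[keep],
               stringsAsFactors = FALSE),
    n_self_loops = sum(self), n_nonpositive = sum(nonpos)
  )
}

#' Build a gene interaction network
#'
#' Constructs a simple undirected weighted graph from an edge list.
#' When `restrict_to` is supplied only edges with both endpoints in that
#' gene set are kept (this is how the network is limited to the
#' integrated DEG set). Duplicate unordered pairs are collapsed keeping
#' the maximum score, self-loops are removed, and nodes left without any
#' edge are absent from the result -- every node of a built network has
#' degree at least one.
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `score` (as
#'   from [read_edge_list()]), or a 3-column data frame in that order.
#' @param restrict_to optional character vector of gene symbols.
#' @return A `gene_network` object wrapping an igraph graph with a
#'   `weight` edge attribute in (0, 1].
#' @export
build_network <- function(edges, restrict_to = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 3L)
    stop("'edges' must be a data frame with >= 3 columns")
  names(edges)[1:3] <- c("gene_a", "gene_b", "score")
  a <- toupper(as.character(edges$gene_a))
  b <- toupper(as.character(edges$gene_b))
  s <- as.numeric(edges$score)
  keep <- a != b & s > 0
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (!is.null(restrict_to)) {
    restrict_to <- toupper(restrict_to)
    keep <- a %in% restrict_to & b %in% restrict_to
    a <- a[keep]; b <- b[keep]; s <- s[keep]
  }
  # canonical unordered pair, max-score deduplication
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (length(lo)) {
    key <- paste(lo, hi, sep = "\r")
    mx <- tapply(s, key, max)
    pairs <- strsplit(names(mx), "\r", fixed = TRUE)
    lo <- vapply(pairs, `[[`, character(1), 1L)
    hi <- vapply(pairs, `[[`, character(1), 2L)
    s <- as.numeric(mx)
    o <- order(lo, hi)
    lo <- lo[o]; hi <- hi[o]; s <- s[o]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, weight = s, stringsAsFactors = FALSE),
    directed = FALSE
  )
  structure(list(graph = g), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  g <- x$graph
  cat("<gene_network> ", igraph::vcount(g), " nodes, ",
      igraph::ecount(g), " edges, ",
      igraph::count_components(g), " component(s)\n", sep = "")
  invisible(x)
}

#' Node symbols of a network
#' @param net a `gene_network`.
#' @return character vector of gene symbols.
#' @export
network_nodes <- function(net) {
  igraph::V(as_gene_graph(net))$name
}

#' Edges of a network as a canonical data frame
#'
#' Endpoints are sorted within each row and rows are sorted
#' lexicographically, so identical networks always serialize to identical
#' tables.
#'
#' @param net a `gene_network`.
#' @return data frame `gene_a`, `gene_b`, `score`.
#' @export
network_edges <- function(net) {
  g <- as_gene_graph(net)
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  lo <- pmin(el[, 1L], el[, 2L]); hi <- pmax(el[, 1L], el[, 2L])
  out <- data.frame(gene_a = lo, gene_b = hi,
                    score = igraph::E(g)$weight,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_gene_graph <- function(net) {
  if (inherits(net, "gene_network")) return(net$graph)
  if (inherits(net, "igraph")) return(net)
  stop("expected a gene_network or igraph object")
}

#' Write a network to disk
#'
#' `.graphml` paths are written as GraphML; anything else as the
#' canonical 3-column TSV of [network_edges()].
#'
#' @param net a `gene_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::write_graph(as_gene_graph(net), path, format = "graphml")
  } else {
    utils::write.table(network_edges(net), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path a `.graphml` file or a 3-column TSV edge list.
#' @return a `gene_network`.
#' @export
read_network <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    df <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(gene_a = df$from, gene_b = df$to,
                        score = if ("weight" %in% names(df)) df$weight
                                else 1,
                        stringsAsFactors = FALSE)
    build_network(edges)
  } else {
    build_network(read_edge_list(path, dialect = "generic"))
  }
}
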