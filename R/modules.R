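#' Maximal cliques of a network
#'
#' Enumerates every maximal clique of size >= `min_size` (a clique not
#' contained in any larger clique), each reported once as a sorted vector
#' of symbols, with the clique list itself sorted canonically.
#'
#' @param net a `gene_network` or igraph graph.
#' @param min_size smallest clique size reported (default 2).
#' @return list of character vectors, class `clique_set`.
#' @export
maximal_cliques <- function(net, min_size = 2) {
  g <- as_gene_graph(net)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  keys <- vapply(cl, paste, character(1), collapse = "|")
  structure(cl[order(keys)], class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  sizes <- lengths(x)
  cat("<clique_set> ", length(x), " maximal cliques",
      if (length(x)) paste0(" (sizes ", min(sizes), "-", max(sizes), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Maximal Clique Centrality
#'
#' MCC of a node is the sum of `(|C| - 1)!` over the maximal cliques `C`
#' that contain it; a node belonging to no clique scores 0. Nodes that
#' sit in many or large cliques get large scores, which makes MCC a hub
#' detector tuned to locally dense neighborhoods.
#'
#' @param net a `gene_network` or igraph graph.
#' @param cliques optional precomputed [maximal_cliques()] result.
#' @return named numeric vector of MCC scores, one per node of `net`.
#' @export
mcc_scores <- function(net, cliques = NULL) {
  g <- as_gene_graph(net)
  if (is.null(cliques)) cliques <- maximal_cliques(g)
  mcc <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  for (cl in cliques) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1L)
  }
  mcc
}

#' Density (cliqueness) of a node set
#'
#' Number of induced edges divided by the number of node pairs,
#' `E(G) / choose(|V(G)|, 2)`; equals 1 exactly when the set is a clique.
#' This is the score that decides whether a candidate module is kept
#' while a dense subgraph is grown.
#'
#' @param net a `gene_network` or igraph graph.
#' @param node_set character vector of >= 2 node symbols.
#' @return density in \[0, 1\].
#' @export
cliqueness <- function(net, node_set) {
  node_set <- unique(node_set)
  if (length(node_set) < 2L) stop("node set must contain >= 2 nodes")
  g <- as_gene_graph(net)
  sub <- igraph::induced_subgraph(g, node_set)
  igraph::ecount(sub) / choose(length(node_set), 2)
}

#' Mine high-density subgraphs from MCC hub seeds
#'
#' The top `n_hubs` nodes by MCC are taken as hubs (ties broken by
#' symbol). Each hub seeds a module with its largest maximal clique
#' (ties: the lexicographically smallest set), which is then grown
#' greedily: at each step the neighboring node whose addition gives the
#' highest cliqueness is added, provided (a) the enlarged set still has
#' cliqueness >= `theta` and (b) the candidate is adjacent to at least
#' `theta` times the current module size -- the quasi-clique
#' connectivity condition, which stops a dense core from accreting
#' loosely attached background nodes. Growth stops when no neighbor
#' qualifies.
#' Equal-gain ties go to the smaller gene symbol, so the procedure is
#' deterministic. Modules smaller than `min_size` are discarded, and
#' near-duplicate modules (Jaccard similarity >= 0.8) are merged keeping
#' the larger; overlaps below that threshold are allowed, so one gene can
#' appear in several modules.
#'
#' @param net a `gene_network` or igraph graph.
#' @param n_hubs number of MCC hub seeds (default 10).
#' @param theta cliqueness threshold in (0, 1] (default 0.6).
#' @param min_size smallest module reported (default 3).
#' @return list of `dense_module` objects, each with elements `nodes`
#'   (sorted symbols), `edge_count`, `cliqueness`, `seed_hub` and `trace`
#'   (the accepted additions in order); sorted by decreasing size then
#'   by first symbol.
#' @export
mine_dense_modules <- function(net, n_hubs = 10, theta = 0.6,
                               min_size = 3) {
  g <- as_gene_graph(net)
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  cliques <- maximal_cliques(g)
  if (length(cliques) == 0L ||
      max(lengths(cliques)) < min_size) return(list())
  mcc <- mcc_scores(g, cliques)
  hubs <- names(mcc)[order(-mcc, names(mcc))]
  hubs <- hubs[seq_len(min(n_hubs, length(hubs)))]

  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, function(v) igraph::V(g)$name[v])
  names(adj) <- igraph::V(g)$name

  modules <- lapply(hubs, function(h) {
    mine <- cliques[vapply(cliques, function(cl) h %in% cl, logical(1))]
    if (length(mine) == 0L) return(NULL)
    # largest clique; ties -> lexicographically smallest sorted set
    sz <- lengths(mine)
    cand <- mine[sz == max(sz)]
    keys <- vapply(cand, paste, character(1), collapse = "|")
    seed <- cand[[order(keys)[1L]]]
    grow_module(g, adj, seed, h, theta)
  })
  modules <- Filter(function(m) !is.null(m) && length(m$nodes) >= min_size,
                    modules)
  dedupe_modules(modules)
}

grow_module <- function(g, adj, seed, hub, theta) {
  nodes <- seed
  trace <- character(0)
  if (cliqueness_fast(g, nodes) < theta) return(NULL)
  repeat {
    cand <- setdiff(sort(unique(unlist(adj[nodes], use.names = FALSE))),
                    nodes)
    if (length(cand) == 0L) break
    scores <- vapply(cand, function(x)
      cliqueness_fast(g, c(nodes, x)), numeric(1))
    ties <- vapply(cand, function(x)
      sum(adj[[x]] %in% nodes), numeric(1))
    ok <- scores >= theta & ties >= theta * length(nodes)
    if (!any(ok)) break
    best <- cand[ok][which.max(scores[ok])]   # cand sorted: ties -> smaller
    nodes <- c(nodes, best)
    trace <- c(trace, best)
  }
  nodes <- sort(nodes)
  structure(
    list(nodes = nodes,
         edge_count = igraph::ecount(igraph::induced_subgraph(g, nodes)),
         cliqueness = cliqueness_fast(g, nodes),
         seed_hub = hub,
         trace = trace),
    class = "dense_module"
  )
}

cliqueness_fast <- function(g, nodes) {
  igraph::ecount(igraph::induced_subgraph(g, nodes)) /
    choose(length(nodes), 2)
}

dedupe_modules <- function(modules) {
  if (length(modules) <= 1L) return(modules)
  ord <- order(-vapply(modules, function(m) length(m$nodes), integer(1)),
               vapply(modules, function(m) m$nodes[1L], character(1)))
  modules <- modules[ord]
  kept <- list()
  for (m in modules) {
    dup <- any(vapply(kept, function(k) {
      jaccard(m$nodes, k$nodes) >= 0.8
    }, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- m
  }
  kept
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' @export
print.dense_module <- function(x, ...) {
  cat("<dense_module> ", length(x$nodes), " nodes, ",
      x$edge_count, " edges, cliqueness ",
      format(round(x$cliqueness, 3)), " (seed hub ", x$seed_hub, ")\n",
      sep = "")
  cat("  ", paste(x$nodes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize mined modules
#'
#' Writes the module list either as JSON (node lists, edge counts,
#' cliqueness, seed and growth trace) or as a two-column TSV
#' (`module_id`, `gene`), chosen by the file extension.
#'
#' @param modules list returned by [mine_dense_modules()].
#' @param path output path ending in `.json` or `.tsv`.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- lapply(modules, function(m)
      list(nodes = m$nodes, edge_count = m$edge_count,
           cliqueness = m$cliqueness, seed_hub = m$seed_hub,
           trace = m$trace))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    rows <- do.call(rbind, c(list(
      data.frame(module_id = integer(0), gene = character(0))),
      lapply(seq_along(modules), function(i)
        data.frame(module_id = i, gene = modules[[i]]$nodes,
                   stringsAsFactors = FALSE))))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
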