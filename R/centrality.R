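#' Node centralities and the Normalized Centrality Measure
#'
#' Computes, for every node of a gene network, the five classical
#' centralities and the composite NCM score:
#'
#' * `DC` -- degree centrality, `deg(v) / (n - 1)` with `n` the size of
#'   the node's connected component;
#' * `BC` -- betweenness, the unnormalized sum over unordered node pairs
#'   of the fraction of shortest paths passing through `v`;
#' * `CC` -- closeness in its farness form: the mean shortest-path
#'   distance from `v` to every other node of its component (smaller =
#'   more central);
#' * `CLC` -- local clustering coefficient, `2e / (k(k-1))` with `k`
#'   neighbors and `e` edges among them (0 when `k < 2`);
#' * `EC` -- eccentricity centrality, the reciprocal of the largest
#'   distance from `v` to any node of its component;
#' * `NCM` -- `(BC/BCmax + DC/DCmax) / (CC/CCmax)`, with the maxima taken
#'   over the whole network. The betweenness term is 0 by convention when
#'   `BCmax = 0` (e.g. complete graphs). Larger NCM = more important:
#'   NCM rewards nodes that carry many shortest paths and many direct
#'   neighbors while sitting close (small farness) to the rest of the
#'   network.
#'
#' Shortest paths are hop counts by default. With `weighted = TRUE` the
#' edge length is `1 - score`, so high-confidence interactions are short;
#' scores of exactly 1 are given a tiny positive length (1e-6) to keep
#' path algorithms well defined. Degree and clustering coefficient are
#' topological in both modes.
#'
#' Disconnected networks are handled per component: `DC`, `CC` and `EC`
#' use the component size for `n` and restrict distances to the
#' component, and `BC` sums only over same-component pairs, while the
#' NCM maxima span the whole network so that a single global ranking
#' results.
#'
#' @param net a `gene_network` (or igraph graph).
#' @param weighted use `1 - score` edge lengths for shortest paths.
#' @return A `centrality_table`: data frame with columns `node`,
#'   `component`, `DC`, `BC`, `CC`, `CLC`, `EC`, `NCM` and rank columns
#'   `rank_DC` ... `rank_NCM` (rank 1 = most central under each measure's
#'   own sort direction), ordered by node symbol.
#' @export
centrality_table <- function(net, weighted = FALSE) {
  g <- as_gene_graph(net)
  n <- igraph::vcount(g)
  if (n < 2L) stop("network must have >= 2 nodes")
  comp <- igraph::components(g)
  if (any(comp$csize < 2L))
    stop("singleton nodes present; build the network with build_network()")
  nodes <- igraph::V(g)$name

  ew <- NULL
  if (weighted) {
    ew <- 1 - igraph::E(g)$weight
    ew[ew <= 0] <- 1e-6
  }

  DC <- igraph::degree(g) / (comp$csize[comp$membership] - 1)
  BC <- igraph::betweenness(g, directed = FALSE,
                            weights = if (weighted) ew else NA)
  d <- igraph::distances(g, weights = if (weighted) ew else NA)
  d[is.infinite(d)] <- NA_real_
  CC <- rowSums(d, na.rm = TRUE) / (comp$csize[comp$membership] - 1)
  EC <- 1 / apply(d, 1L, max, na.rm = TRUE)
  CLC <- igraph::transitivity(g, type = "local", isolates = "zero")

  BCmax <- max(BC); DCmax <- max(DC); CCmax <- max(CC)
  bc_term <- if (BCmax > 0) BC / BCmax else rep(0, n)
  NCM <- (bc_term + DC / DCmax) / (CC / CCmax)

  out <- data.frame(node = nodes, component = comp$membership,
                    DC = DC, BC = BC, CC = CC, CLC = CLC, EC = EC,
                    NCM = NCM, stringsAsFactors = FALSE)
  # rank 1 = most central; CC ranks ascending (small farness first),
  # everything else descending; ties share the position of the
  # lexicographically first symbol
  rank_of <- function(x, decreasing) {
    ord <- order(if (decreasing) -x else x, out$node)
    r <- integer(n); r[ord] <- seq_len(n); r
  }
  out$rank_DC <- rank_of(out$DC, TRUE)
  out$rank_BC <- rank_of(out$BC, TRUE)
  out$rank_CC <- rank_of(out$CC, FALSE)
  out$rank_CLC <- rank_of(out$CLC, TRUE)
  out$rank_EC <- rank_of(out$EC, TRUE)
  out$rank_NCM <- rank_of(out$NCM, TRUE)
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, weighted = weighted,
            class = c("centrality_table", "data.frame"))
}

#' @export
print.centrality_table <- function(x, ...) {
  cat("<centrality_table> ", nrow(x), " nodes",
      if (isTRUE(attr(x, "weighted"))) " (weighted paths)", "\n",
      sep = "")
  if (!is.null(x$rank_NCM)) {
    top <- x$node[order(x$rank_NCM)][seq_len(min(5L, nrow(x)))]
    cat("  top by NCM: ", paste(top, collapse = ", "), "\n", sep = "")
  }
  print(as.data.frame(utils::head(x, 10L)))
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}

#' Top-k nodes under one centrality measure
#'
#' Sort directions follow each measure's reading: DC, BC, CLC and NCM
#' descending (large = central); CC ascending (small farness = central);
#' EC descending by default, since the eccentricity centrality is stored
#' as a reciprocal and large values mean small eccentricity -- pass
#' `ec_direction = "asc"` for the opposite convention. Ties are broken by
#' gene symbol so the ranking is deterministic.
#'
#' @param table a [centrality_table()].
#' @param measure one of `"DC"`, `"BC"`, `"CC"`, `"CLC"`, `"EC"`,
#'   `"NCM"` (case-insensitive).
#' @param k how many nodes; values above the node count return all nodes.
#' @param ec_direction sort direction used for EC only.
#' @return character vector of node symbols, most central first.
#' @export
rank_nodes <- function(table, measure, k,
                       ec_direction = c("desc", "asc")) {
  measure <- toupper(measure)
  ec_direction <- match.arg(ec_direction)
  if (!measure %in% c("DC", "BC", "CC", "CLC", "EC", "NCM"))
    stop("unknown measure: ", measure)
  if (k < 0) stop("k must be >= 0")
  x <- table[[measure]]
  decreasing <- switch(measure,
    CC = FALSE,
    EC = ec_direction == "desc",
    TRUE)
  ord <- order(if (decreasing) -x else x, table$node)
  k <- min(k, nrow(table))
  table$node[ord][seq_len(k)]
}
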