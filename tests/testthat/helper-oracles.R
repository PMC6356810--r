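# Naive enumeration oracles, independent of the production code paths.
# Shortest paths are found by exhaustive depth-first enumeration of
# simple paths (with a running upper bound for pruning), never by
# BFS/Dijkstra/Brandes; cliques by subset checking; BH and the
# hypergeometric tail from their definitions.

# All-pairs shortest-path census by simple-path enumeration.
# Returns dist (n x n), sigma (path counts) and through[[i]][[j]]:
# named counts of shortest i-j paths passing through each interior node.
oracle_sp_census <- function(net, weighted = FALSE) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  ed <- network_edges(net)
  ia <- match(ed$gene_a, nodes); ib <- match(ed$gene_b, nodes)
  len <- if (weighted) pmax(1 - ed$score, 1e-6) else rep(1, nrow(ed))
  adj <- rep(list(integer(0)), n)
  wt <- rep(list(numeric(0)), n)
  for (e in seq_len(nrow(ed))) {
    adj[[ia[e]]] <- c(adj[[ia[e]]], ib[e])
    wt[[ia[e]]] <- c(wt[[ia[e]]], len[e])
    adj[[ib[e]]] <- c(adj[[ib[e]]], ia[e])
    wt[[ib[e]]] <- c(wt[[ib[e]]], len[e])
  }
  eps <- 1e-9
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(dist) <- 0
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(sigma) <- 1
  through <- vector("list", n)

  for (i in seq_len(n - 1L)) {
    through[[i]] <- vector("list", n)
    for (j in seq.int(i + 1L, n)) {
      env <- new.env()
      env$best <- Inf
      env$paths <- list()
      visit <- function(v, visited, acc) {
        if (acc > env$best + eps) return(invisible())
        if (v == j) {
          if (acc < env$best - eps) {
            env$best <- acc
            env$paths <- list()
          }
          if (abs(acc - env$best) <= eps)
            env$paths[[length(env$paths) + 1L]] <- visited
          return(invisible())
        }
        for (k in seq_along(adj[[v]])) {
          u <- adj[[v]][k]
          if (!(u %in% visited))
            visit(u, c(visited, u), acc + wt[[v]][k])
        }
        invisible()
      }
      visit(i, i, 0)
      if (length(env$paths)) {
        dist[i, j] <- dist[j, i] <- env$best
        sigma[i, j] <- sigma[j, i] <- length(env$paths)
        interior <- unlist(lapply(env$paths, function(p)
          p[-c(1L, length(p))]))
        cnt <- numeric(n)
        if (length(interior)) {
          tb <- table(interior)
          cnt[as.integer(names(tb))] <- as.numeric(tb)
        }
        through[[i]][[j]] <- cnt
      }
    }
  }
  list(nodes = nodes, dist = dist, sigma = sigma, through = through)
}

# The five classical measures from the census alone.
oracle_centralities <- function(net, weighted = FALSE) {
  census <- oracle_sp_census(net, weighted = weighted)
  nodes <- census$nodes
  n <- length(nodes)
  d <- census$dist
  comp_mates <- lapply(seq_len(n), function(v) which(is.finite(d[v, ])))

  ed <- network_edges(net)
  ia <- match(ed$gene_a, nodes); ib <- match(ed$gene_b, nodes)
  deg <- tabulate(c(ia, ib), nbins = n)
  adjacent <- matrix(FALSE, n, n)
  adjacent[cbind(ia, ib)] <- TRUE
  adjacent[cbind(ib, ia)] <- TRUE

  DC <- vapply(seq_len(n), function(v)
    deg[v] / (length(comp_mates[[v]]) - 1L), numeric(1))
  CC <- vapply(seq_len(n), function(v) {
    others <- setdiff(comp_mates[[v]], v)
    mean(d[v, others])
  }, numeric(1))
  EC <- vapply(seq_len(n), function(v) {
    others <- setdiff(comp_mates[[v]], v)
    1 / max(d[v, others])
  }, numeric(1))
  BC <- numeric(n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    cnt <- census$through[[i]][[j]]
    if (is.null(cnt)) next
    BC <- BC + cnt / census$sigma[i, j]
  }
  CLC <- vapply(seq_len(n), function(v) {
    nb <- which(adjacent[v, ])
    k <- length(nb)
    if (k < 2L) return(0)
    e <- sum(adjacent[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
  data.frame(node = nodes, DC = DC, BC = BC, CC = CC, CLC = CLC,
             EC = EC, stringsAsFactors = FALSE)
}

# Maximal cliques by checking every subset of size >= 2.
oracle_max_cliques <- function(net) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  ed <- network_edges(net)
  adjacent <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  adjacent[cbind(ed$gene_a, ed$gene_b)] <- TRUE
  adjacent[cbind(ed$gene_b, ed$gene_a)] <- TRUE
  is_clique <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    all(adjacent[idx, idx][upper.tri(diag(length(idx)))])
  }
  out <- list()
  for (size in 2:n) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      if (!is_clique(idx)) next
      extendable <- any(vapply(setdiff(seq_len(n), idx), function(u)
        all(adjacent[u, idx]), logical(1)))
      if (!extendable) out[[length(out) + 1L]] <- sort(nodes[idx])
    }
  }
  keys <- vapply(out, paste, character(1), collapse = "|")
  out[order(keys)]
}

# BH step-up straight from the definition: sort, adj_(i) = min_{j>=i}
# m p_(j) / j, capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Hypergeometric upper tail by summing the pmf written with choose().
oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  xs <- k:min(K, n)
  if (length(xs) == 0L || k > min(K, n)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
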