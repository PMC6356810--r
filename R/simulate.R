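#' Specification for a synthetic two-group expression matrix
#'
#' Describes a tumor-vs-normal style microarray experiment on the log2
#' scale: per-gene baselines drawn from Normal(8, 1) to mimic the
#' intensity spread of a log2 microarray, Gaussian sample noise, and a
#' planted shift of `true_lfc` log2 units added to the case group of the
#' first `n_de` genes.
#'
#' @param n_genes total number of genes.
#' @param n_de number of genes carrying the planted shift.
#' @param true_lfc planted log2 fold change (case minus control).
#' @param noise_sd standard deviation of the per-sample Gaussian noise
#'   (log2 units), must be > 0.
#' @param n_per_group samples per group, at least 2.
#' @param seed integer seed; mandatory so every simulation is
#'   reproducible.
#' @return list of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes, n_de, true_lfc, noise_sd,
                                n_per_group, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n_de < 0 || n_de > n_genes)
    stop("'n_de' must satisfy 0 <= n_de <= n_genes")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (n_per_group < 2) stop("'n_per_group' must be >= 2")
  structure(list(n_genes = as.integer(n_genes), n_de = as.integer(n_de),
                 true_lfc = true_lfc, noise_sd = noise_sd,
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' Simulate a two-group expression dataset with planted DE genes
#'
#' @param spec an [expression_sim_spec()] (or a list/JSON-derived list
#'   with the same fields).
#' @return list with `dataset` (an [expression_dataset()]) and `truth`, a
#'   data frame of per-gene planted log2 fold changes (0 for null genes).
#' @export
simulate_expression <- function(spec) {
  if (!inherits(spec, "expression_sim_spec"))
    spec <- do.call(expression_sim_spec, spec[c(
      "n_genes", "n_de", "true_lfc", "noise_sd", "n_per_group", "seed")])
  with_seed(spec$seed, {
    ng <- spec$n_genes; np <- spec$n_per_group
    genes <- sprintf("G%0*d", nchar(ng), seq_len(ng))
    samples <- c(sprintf("CASE_%02d", seq_len(np)),
                 sprintf("CTRL_%02d", seq_len(np)))
    groups <- stats::setNames(rep(c("case", "control"), each = np),
                              samples)
    baseline <- stats::rnorm(ng, mean = 8, sd = 1)
    vals <- matrix(stats::rnorm(ng * 2L * np, mean = 0,
                                sd = spec$noise_sd),
                   nrow = ng, ncol = 2L * np,
                   dimnames = list(genes, samples))
    vals <- vals + baseline
    lfc <- c(rep(spec$true_lfc, spec$n_de),
             rep(0, ng - spec$n_de))
    vals[, seq_len(np)] <- vals[, seq_len(np)] + lfc
    list(dataset = expression_dataset(vals, groups,
                                      dataset_id = paste0("sim", spec$seed)),
         truth = data.frame(gene = genes, true_lfc = lfc,
                            stringsAsFactors = FALSE))
  })
}

#' Specification for a random network with planted dense modules
#'
#' A sparse Erdos-Renyi background with dense planted pockets: node pairs
#' inside a planted module are wired with that module's density, all
#' other pairs with `p_background`. This emulates the shape of a DEG
#' interaction network -- sparse overall, with a few near-clique
#' neighborhoods.
#'
#' @param n_nodes number of nodes.
#' @param p_background background edge probability.
#' @param planted_modules list of `c(size, density)` pairs; each density
#'   must exceed `p_background` and each size must be >= 3. Modules are
#'   assigned disjoint node blocks.
#' @param seed integer seed, mandatory.
#' @return list of class `network_sim_spec`.
#' @export
network_sim_spec <- function(n_nodes, p_background, planted_modules,
                             seed) {
  if (missing(seed)) stop("'seed' is required")
  if (p_background < 0 || p_background > 1)
    stop("'p_background' must be in [0, 1]")
  planted_modules <- lapply(planted_modules, function(m) {
    m <- as.numeric(m)
    if (length(m) != 2L) stop("each planted module is c(size, density)")
    if (m[1L] < 3) stop("planted module sizes must be >= 3")
    if (m[2L] <= p_background || m[2L] > 1)
      stop("planted densities must be in (p_background, 1]")
    m
  })
  if (sum(vapply(planted_modules, `[[`, numeric(1), 1L)) > n_nodes)
    stop("planted module sizes exceed 'n_nodes'")
  structure(list(n_nodes = as.integer(n_nodes),
                 p_background = p_background,
                 planted_modules = planted_modules,
                 seed = as.integer(seed)),
            class = "network_sim_spec")
}

#' Simulate a network with planted dense modules
#'
#' All edge weights are 1.0. Nodes left isolated by the draw are absent
#' from the built network (as in any [build_network()] result) but still
#' appear in the truth table.
#'
#' @param spec a [network_sim_spec()] (or an equivalent list).
#' @return list with `network` (a `gene_network`), `edges` (the raw edge
#'   data frame before isolated-node removal) and `truth`, a data frame
#'   mapping every node to its planted module id or `"background"`.
#' @export
simulate_network <- function(spec) {
  if (!inherits(spec, "network_sim_spec"))
    spec <- do.call(network_sim_spec, spec[c(
      "n_nodes", "p_background", "planted_modules", "seed")])
  with_seed(spec$seed, {
    n <- spec$n_nodes
    nodes <- sprintf("N%0*d", nchar(n), seq_len(n))
    membership <- rep("background", n)
    at <- 1L
    for (i in seq_along(spec$planted_modules)) {
      size <- as.integer(spec$planted_modules[[i]][1L])
      membership[at:(at + size - 1L)] <- paste0("module", i)
      at <- at + size
    }
    pairs <- utils::combn(n, 2L)
    same <- membership[pairs[1L, ]] == membership[pairs[2L, ]] &
      membership[pairs[1L, ]] != "background"
    prob <- rep(spec$p_background, ncol(pairs))
    for (i in seq_along(spec$planted_modules)) {
      inside <- same & membership[pairs[1L, ]] == paste0("module", i)
      prob[inside] <- spec$planted_modules[[i]][2L]
    }
    keep <- stats::runif(ncol(pairs)) < prob
    edges <- data.frame(gene_a = nodes[pairs[1L, keep]],
                        gene_b = nodes[pairs[2L, keep]],
                        score = 1.0, stringsAsFactors = FALSE)
    list(network = build_network(edges),
         edges = edges,
         truth = data.frame(node = nodes, module = membership,
                            stringsAsFactors = FALSE))
  })
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
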