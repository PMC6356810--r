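# Small graph fixtures, built in code.

edge_df <- function(a, b, score = 1) {
  data.frame(gene_a = a, gene_b = b, score = score,
             stringsAsFactors = FALSE)
}

star5 <- function() {
  build_network(edge_df(rep("C", 4), paste0("L", 1:4), 0.5))
}

k4 <- function() {
  build_network(edge_df(c("A", "A", "A", "B", "B", "C"),
                        c("B", "C", "D", "C", "D", "D")))
}

path3 <- function() {
  build_network(edge_df(c("A", "B"), c("B", "C")))
}

# triangle A-B-C plus pendant D attached to C
tri_pendant <- function() {
  build_network(edge_df(c("A", "A", "B", "C"),
                        c("B", "C", "C", "D")))
}

# two triangles {A,B,C} and {B,C,D} sharing edge B-C
shared_edge_triangles <- function() {
  build_network(edge_df(c("A", "A", "B", "B", "C"),
                        c("B", "C", "C", "D", "D")))
}

# Erdos-Renyi draw as an edge data frame; node symbols V01, V02, ...
random_edge_df <- function(n, p, scores = NULL) {
  nodes <- sprintf("V%02d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  s <- if (is.null(scores)) rep(1, sum(keep))
       else sample(scores, sum(keep), replace = TRUE)
  edge_df(nodes[pairs[1L, keep]], nodes[pairs[2L, keep]], s)
}

# a random graph guaranteed non-empty (redraws until it has an edge)
random_network <- function(n, p, scores = NULL) {
  repeat {
    ed <- random_edge_df(n, p, scores)
    if (nrow(ed) > 0L) return(build_network(ed))
  }
}
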