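# Shared fixture builders: everything is generated in code at test time.

# Erdos-Renyi test graph with stable vertex names.
random_test_graph <- function(n, p = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# Attach simulated differential-edge p-values (as left by edge filtering
# at alpha = 0.05) to a graph.
with_edge_pvalues <- function(g, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (igraph::gsize(g) > 0) {
    igraph::E(g)$p_value <- stats::runif(igraph::gsize(g), 1e-12, 0.05)
  }
  g
}

# Small named graph from an edge matrix.
graph_from_pairs <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Write a temporary TSV file from lines.
write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Bivariate normal sample with correlation rho (unit marginals).
rbinorm <- function(n, rho) {
  x <- stats::rnorm(n)
  cbind(x, rho * x + sqrt(1 - rho^2) * stats::rnorm(n))
}
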