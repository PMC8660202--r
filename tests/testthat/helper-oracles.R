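# Independent oracles used to cross-check the package's own implementations.

# Benjamini-Hochberg step-up, written directly from the definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j), back in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws
# (feasible for N <= 12): fraction of draws with >= k members of the term.
hyper_enum_oracle <- function(k, K, n, N) {
  universe <- seq_len(N)
  in_term <- universe <= K
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(in_term[draws], nrow = n))
  mean(hits >= k)
}

# Betweenness by explicit enumeration of all shortest paths per unordered
# pair, via igraph machinery (independent of the package's Brandes code).
betweenness_enum_oracle <- function(g) {
  n <- igraph::vcount(g)
  bc <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (n < 3) return(bc)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t)$res)
      if (length(paths) == 0) next
      for (p in paths) {
        inner <- setdiff(as.integer(p), c(s, t))
        bc[inner] <- bc[inner] + 1 / length(paths)
      }
    }
  }
  bc
}

# Dominant eigenvector via dense symmetric eigendecomposition, max-rescaled.
eigenvector_eigen_oracle <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
  stats::setNames(v / max(v), igraph::V(g)$name)
}

# Random simple undirected graph with at least one edge.
random_small_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
    if (igraph::ecount(g) >= 1) return(g)
  }
}
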