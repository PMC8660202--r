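# Small programmatic fixtures.

# Interaction tibble from a compact string spec: "A B 0.9; B C 0.7".
itable <- function(spec) {
  rows <- strsplit(trimws(strsplit(spec, ";")[[1]]), "\\s+")
  tibble::tibble(
    protein1 = vapply(rows, `[[`, "", 1),
    protein2 = vapply(rows, `[[`, "", 2),
    combined_score = as.numeric(vapply(rows, `[[`, "", 3))
  )
}

# Tiny two-group expression fixture from explicit per-gene case/control
# values: a list of lists with case/control numeric vectors.
expr_fixture <- function(genes) {
  n1 <- length(genes[[1]]$case); n2 <- length(genes[[1]]$control)
  mat <- t(vapply(genes, function(g) c(g$case, g$control),
                  numeric(n1 + n2)))
  sample_ids <- c(sprintf("case_%d", seq_len(n1)),
                  sprintf("ctrl_%d", seq_len(n2)))
  expr <- tibble::as_tibble(as.data.frame(mat))
  names(expr) <- sample_ids
  expr <- dplyr::bind_cols(
    tibble::tibble(gene = names(genes) %||% sprintf("g%d", seq_along(genes))),
    expr)
  samples <- tibble::tibble(
    sample_id = sample_ids,
    group = rep(c("case", "control"), c(n1, n2)))
  list(expression = expr, samples = samples)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic DEG table from explicit gene/status pairs.
deg_fixture <- function(over = character(), under = character(),
                        ns = character()) {
  genes <- c(over, under, ns)
  tibble::tibble(
    gene = genes,
    log2FC = c(rep(1, length(over)), rep(-1, length(under)),
               rep(0, length(ns))),
    p_adj = c(rep(0.01, length(over) + length(under)), rep(0.9, length(ns))),
    status = c(rep("over", length(over)), rep("under", length(under)),
               rep("ns", length(ns)))
  )
}

star_graph <- function(leaves = 5) {
  g <- igraph::make_star(leaves + 1, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("center", sprintf("leaf%d", seq_len(leaves)))
  g
}

path3_graph <- function() {
  igraph::graph_from_literal(A - B, B - C)
}

triangle_graph <- function() {
  igraph::graph_from_literal(A - B, B - C, A - C)
}
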