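# Degree / betweenness / eigenvector centrality and the hub-bottleneck-
# switch (HBS) classification. Betweenness and eigenvector are authored here
# with the exact conventions the classification assumes: fractional shortest-
# path counting over unordered pairs with endpoints excluded and no
# normalisation, and a dominant-eigenvector loading rescaled to max = 1.
# Graphs are treated as unweighted: confidence was already filtered at build
# time.

as_centrality_graph <- function(net) {
  if (igraph::is_igraph(net)) return(net)
  if (is.data.frame(net)) {
    stopifnot(ncol(net) >= 2)
    e <- tibble(protein1 = as.character(net[[1]]),
                protein2 = as.character(net[[2]]),
                combined_score = 1)
    return(as_ppi_network(
      tibble(node = unique(c(e$protein1, e$protein2)), shell = 0L),
      canonical_edges(e)
    ))
  }
  abort("net must be an igraph or an edge data frame")
}

#' Degree centrality (adjacent-neighbour count)
#'
#' @param net A `ppi_network`/igraph, or an edge data frame (two identifier
#'   columns).
#' @return Named integer vector, one entry per node.
#' @export
degree_centrality <- function(net) {
  g <- as_centrality_graph(net)
  d <- igraph::degree(g, loops = FALSE)
  stats::setNames(as.integer(d), igraph::V(g)$name)
}

#' Betweenness centrality (Brandes' algorithm, unnormalised)
#'
#' For each node v, the sum over unordered pairs \{s, t\} (s, t distinct
#' from v) of the fraction of shortest s-t paths passing through v, computed
#' by breadth-first search with Brandes' dependency accumulation. Pairs in
#' different components contribute 0. No normalisation is applied — the raw
#' score — but note any affine rescaling leaves the above-average HBS
#' classification unchanged.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  g <- as_centrality_graph(net)
  n <- igraph::vcount(g)
  bc <- numeric(n)
  if (n == 0) return(stats::setNames(bc, character(0)))
  adj <- lapply(igraph::as_adj_list(g, mode = "all"),
                function(x) unique(as.integer(x)))
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    pred <- vector("list", n)
    queue <- integer(n); queue[1] <- s; head_i <- 1L; tail_i <- 1L
    visited <- integer(0)
    while (head_i <= tail_i) {
      v <- queue[head_i]; head_i <- head_i + 1L
      visited <- c(visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail_i <- tail_i + 1L; queue[tail_i] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(visited)) {
      for (v in pred[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  stats::setNames(bc / 2, igraph::V(g)$name)
}

#' Eigenvector centrality (power iteration, max-rescaled)
#'
#' Power iteration from a uniform positive start, L2-normalised each step,
#' stopping when the maximum absolute change falls below 1e-10 or after 1000
#' iterations; the output is rescaled so the maximum loading equals 1. The
#' iteration runs on the shifted operator A + I, which has the same
#' eigenvectors as A with the spectrum moved strictly positive, so bipartite
#' graphs (whose +/- extreme eigenvalue pair makes plain iteration
#' oscillate) converge too. On disconnected graphs the loadings are computed
#' on the full adjacency: nodes outside the dominant component receive ~0,
#' and a warning is emitted.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector in `[0, 1]` with maximum 1.
#' @export
eigenvector_centrality <- function(net) {
  g <- as_centrality_graph(net)
  assert_that(igraph::ecount(g) >= 1,
              "eigenvector centrality is undefined on an edgeless graph")
  if (igraph::count_components(g) > 1) {
    warn(paste("graph has more than one component;",
               "eigenvector loadings concentrate on the dominant one"))
  }
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(1000)) {
    y <- as.numeric(A %*% x) + x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < 1e-10) { x <- y; break }
    x <- y
  }
  stats::setNames(x / max(x), igraph::V(g)$name)
}

#' Per-node centrality report
#'
#' Computes all three centralities on the same node set.
#'
#' @inheritParams degree_centrality
#' @return A `centrality_report` tibble: `node`, `degree`, `betweenness`,
#'   `eigenvector`.
#' @export
centrality_report <- function(net) {
  g <- as_centrality_graph(net)
  deg <- degree_centrality(g)
  out <- tibble(
    node = names(deg),
    degree = as.integer(deg),
    betweenness = unname(betweenness_centrality(g)),
    eigenvector = unname(eigenvector_centrality(g))
  )
  class(out) <- c("centrality_report", class(out))
  out
}

#' Classify hubs, bottlenecks, switches and HBS nodes
#'
#' A node is a Hub if its degree strictly exceeds the network-mean degree, a
#' Bottleneck if its betweenness strictly exceeds the mean betweenness, a
#' Switch if its eigenvector loading strictly exceeds the mean loading, and
#' an HBS — the candidate key regulator — if it is all three at once. Means
#' are taken over ALL nodes of the analysed network; strict inequality means
#' an all-tied graph (e.g. a triangle) flags nothing.
#'
#' @param report A `centrality_report` from [centrality_report()] (or any
#'   data frame with `node`, `degree`, `betweenness`, `eigenvector`).
#' @return The report with logical columns `hub`, `bottleneck`, `switch`,
#'   `hbs` added; the per-metric means attach as attribute `means`.
#' @export
classify_hbs <- function(report) {
  stopifnot(is.data.frame(report))
  assert_that(all(c("node", "degree", "betweenness", "eigenvector") %in%
                    names(report)),
              "report must carry node, degree, betweenness, eigenvector")
  means <- c(degree = mean(report$degree),
             betweenness = mean(report$betweenness),
             eigenvector = mean(report$eigenvector))
  out <- mutate(
    as_tibble(report),
    hub = .data$degree > means[["degree"]],
    bottleneck = .data$betweenness > means[["betweenness"]],
    switch = .data$eigenvector > means[["eigenvector"]],
    hbs = .data$hub & .data$bottleneck & .data$switch
  )
  attr(out, "means") <- means
  class(out) <- c("centrality_report", setdiff(class(out), "centrality_report"))
  out
}

#' Identifiers of the HBS nodes in a classified report
#'
#' @param report Output of [classify_hbs()].
#' @return Character vector of HBS node ids.
#' @export
hbs_nodes <- function(report) {
  assert_that("hbs" %in% names(report), "run classify_hbs() first")
  report$node[report$hbs]
}

#' Write a centrality report and the HBS id list
#'
#' @param report Output of [classify_hbs()].
#' @param path Centrality TSV path.
#' @param hbs_path Optional path for the HBS id list (one id per line).
#' @return Invisibly, `path`.
#' @export
write_centrality <- function(report, path, hbs_path = NULL) {
  readr::write_tsv(as_tibble(report), path)
  if (!is.null(hbs_path)) writeLines(hbs_nodes(report), hbs_path)
  invisible(path)
}
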