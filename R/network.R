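# Scored-interaction network construction: confidence filter, bounded shell
# expansion, iterative re-seeding of unconnected inputs, merge, and the
# grow-to-saturation induced network.

#' Network build parameters
#'
#' Defaults follow the standard interactome-query protocol: interactions with
#' combined confidence below 0.4 are discarded; seed expansion admits at most
#' 20 first-shell and 5 second-shell interactors per query. The saturation
#' parameters (50 first-shell, no second shell) drive
#' [grow_to_saturation()].
#'
#' @param min_confidence Minimum combined score, in `[0, 1]`.
#' @param shell1_max,shell2_max Per-query caps on first/second shell size.
#' @param saturation_shell1,saturation_shell2 Shell caps used while growing
#'   to saturation.
#' @return A `network_config` list.
#' @export
network_config <- function(min_confidence = 0.4, shell1_max = 20L,
                           shell2_max = 5L, saturation_shell1 = 50L,
                           saturation_shell2 = 0L) {
  assert_that(min_confidence >= 0 && min_confidence <= 1,
              "min_confidence must lie in [0, 1]")
  assert_that(all(c(shell1_max, shell2_max, saturation_shell1,
                    saturation_shell2) >= 0), "shell maxima must be >= 0")
  structure(list(min_confidence = min_confidence,
                 shell1_max = as.integer(shell1_max),
                 shell2_max = as.integer(shell2_max),
                 saturation_shell1 = as.integer(saturation_shell1),
                 saturation_shell2 = as.integer(saturation_shell2)),
            class = "network_config")
}

#' Read a scored interaction table
#'
#' Accepts STRING-style TSVs. Scores are auto-scaled: any score column whose
#' values exceed 1 is assumed to use the 0-1000 integer convention and is
#' divided by 1000. Duplicate unordered pairs collapse to one record keeping
#' the maximum score; self-pairs are rejected. If no combined-score column is
#' present but per-channel scores are (e.g. `experiments`, `databases`,
#' `coexpression`), they combine independently as
#' `1 - prod(1 - s_channel)`.
#'
#' @param path TSV with two identifier columns (`protein1`/`protein2` or
#'   `node_a`/`node_b`, else the first two columns) and score column(s).
#' @return Interaction tibble: `protein1`, `protein2`, `combined_score`.
#' @export
read_interaction_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  assert_that(ncol(raw) >= 3, "interaction table needs nodes plus a score")
  nm <- names(raw)
  pick <- function(cands) intersect(cands, nm)[1]
  a_col <- pick(c("protein1", "node_a", "node1"))
  if (is.na(a_col)) a_col <- nm[1]
  b_col <- pick(c("protein2", "node_b", "node2"))
  if (is.na(b_col)) b_col <- nm[2]
  score_col <- pick(c("combined_score", "score"))
  score_cols <- if (!is.na(score_col)) score_col else
    setdiff(nm[vapply(raw, is.numeric, logical(1))], c(a_col, b_col))
  assert_that(length(score_cols) >= 1, "no score column found")
  scores <- as.matrix(raw[, score_cols, drop = FALSE])
  for (j in seq_len(ncol(scores))) {
    if (any(scores[, j] > 1, na.rm = TRUE)) scores[, j] <- scores[, j] / 1000
  }
  bad <- which(rowSums(scores < 0 | scores > 1, na.rm = TRUE) > 0)
  if (length(bad)) {
    abort(sprintf("score outside [0, 1] after scaling at row %d", bad[1]))
  }
  combined <- if (ncol(scores) == 1) scores[, 1] else
    1 - apply(1 - scores, 1, prod)
  a <- as.character(raw[[a_col]]); b <- as.character(raw[[b_col]])
  self <- which(a == b)
  if (length(self)) abort(sprintf("self-interaction at row %d", self[1]))
  canonical_edges(tibble(protein1 = a, protein2 = b,
                         combined_score = combined)) |>
    arrange(.data$protein1, .data$protein2)
}

# Normalise an edge tibble: unordered pair once, no self-loops.
canonical_edges <- function(table) {
  stopifnot(all(c("protein1", "protein2", "combined_score") %in% names(table)))
  out <- tibble(protein1 = pmin(table$protein1, table$protein2),
                protein2 = pmax(table$protein1, table$protein2),
                combined_score = table$combined_score) |>
    filter(.data$protein1 != .data$protein2)
  if (nrow(out) == 0) return(out)
  out |>
    group_by(.data$protein1, .data$protein2) |>
    summarise(combined_score = max(.data$combined_score), .groups = "drop")
}

# Core shell-expansion on tibbles. Returns list(nodes = tibble(node, shell),
# edges = tibble(protein1, protein2, combined_score)).
expand_core <- function(table, seeds, min_confidence, shell1_max, shell2_max) {
  edges <- canonical_edges(table) |>
    filter(.data$combined_score >= min_confidence)
  pick_shell <- function(members, cap) {
    if (cap == 0) return(character(0))
    touch <- edges |>
      filter(xor(.data$protein1 %in% members, .data$protein2 %in% members))
    if (nrow(touch) == 0) return(character(0))
    cand <- tibble(
      node = ifelse(touch$protein1 %in% members, touch$protein2, touch$protein1),
      score = touch$combined_score
    ) |>
      group_by(.data$node) |>
      summarise(score = max(.data$score), .groups = "drop") |>
      arrange(desc(.data$score), .data$node)
    head(cand$node, cap)
  }
  shell1 <- pick_shell(seeds, shell1_max)
  shell2 <- pick_shell(union(seeds, shell1), shell2_max)
  nodes <- tibble(
    node = c(seeds, shell1, shell2),
    shell = rep(0:2, c(length(seeds), length(shell1), length(shell2)))
  )
  kept <- edges |>
    filter(.data$protein1 %in% nodes$node & .data$protein2 %in% nodes$node)
  list(nodes = nodes, edges = kept)
}

# Assemble an igraph from node/edge tibbles with standard attributes.
as_ppi_network <- function(nodes, edges, deg_table = NULL) {
  nodes <- nodes |>
    group_by(.data$node) |>
    summarise(shell = min(.data$shell), .groups = "drop") |>
    arrange(.data$node)
  nodes$is_seed <- nodes$shell == 0
  if (!is.null(deg_table)) {
    idx <- match(nodes$node, deg_table$gene)
    nodes$is_deg <- !is.na(idx) & deg_table$status[idx] != "ns"
    nodes$direction <- ifelse(nodes$is_deg, deg_table$status[idx], "none")
  } else {
    nodes$is_deg <- FALSE
    nodes$direction <- "none"
  }
  edges <- canonical_edges(edges) |>
    arrange(.data$protein1, .data$protein2)
  g <- igraph::graph_from_data_frame(
    rename(edges, from = "protein1", to = "protein2",
           score = "combined_score"),
    directed = FALSE, vertices = nodes
  )
  class(g) <- c("ppi_network", class(g))
  g
}

#' Expand a seed set into its interaction neighbourhood
#'
#' Candidate first-shell interactors are the non-seed nodes with at least one
#' edge of score `>= min_confidence` to a seed, ranked by maximum such score
#' (descending) with ties broken by ascending node id, keeping the top
#' `shell1_max`; the second shell is selected analogously relative to the
#' seeds-plus-first-shell set. The final edge set contains every
#' confidence-qualifying edge among the retained nodes (an "evidence view",
#' not just seed-to-shell spokes), which is what makes downstream centrality
#' meaningful.
#'
#' @param table Interaction tibble (`protein1`, `protein2`,
#'   `combined_score`).
#' @param seeds Character vector of seed identifiers (non-empty).
#' @param config A [network_config()].
#' @return A `ppi_network` igraph with node attributes `shell` (0 = seed,
#'   1, 2), `is_seed`, `is_deg`, `direction` and edge attribute `score`.
#'   Seeds without qualifying edges stay as isolated nodes.
#' @export
expand_seeds <- function(table, seeds, config = network_config()) {
  assert_that(length(seeds) > 0, "seeds must be non-empty")
  seeds <- unique(as.character(seeds))
  res <- expand_core(table, seeds, config$min_confidence,
                     config$shell1_max, config$shell2_max)
  as_ppi_network(res$nodes, res$edges)
}

#' Build the merged per-tissue network by iterative re-seeding
#'
#' Round 1 expands all differentially expressed genes at once. While any
#' input gene is still isolated (degree 0) and the previous round added at
#' least one edge, the isolated inputs are re-submitted as a fresh seed set
#' and the resulting subnetwork is merged in (node/edge union; a node's shell
#' is the minimum over rounds). The loop is bounded: every productive round
#' connects at least one isolated input.
#'
#' @param table Interaction tibble.
#' @param degs A `deg_table` from [call_degs()]; its non-`ns` genes are the
#'   inputs and fill the node attributes `is_deg`/`direction`.
#' @param config A [network_config()].
#' @return A `ppi_network` igraph.
#' @export
build_merged_network <- function(table, degs, config = network_config()) {
  stopifnot(is.data.frame(degs))
  inputs <- degs$gene[degs$status != "ns"]
  assert_that(length(inputs) > 0, "no differentially expressed inputs")
  res <- expand_core(table, inputs, config$min_confidence,
                     config$shell1_max, config$shell2_max)
  nodes <- res$nodes; edges <- res$edges
  added <- nrow(edges)
  edge_key <- function(e) paste(e$protein1, e$protein2)
  repeat {
    connected <- unique(c(edges$protein1, edges$protein2))
    isolated <- setdiff(inputs, connected)
    if (length(isolated) == 0 || added == 0) break
    res <- expand_core(table, isolated, config$min_confidence,
                       config$shell1_max, config$shell2_max)
    new_edges <- res$edges[!edge_key(res$edges) %in% edge_key(edges), ]
    added <- nrow(new_edges)
    nodes <- bind_rows(nodes, res$nodes)
    edges <- bind_rows(edges, new_edges)
  }
  as_ppi_network(nodes, edges, deg_table = degs)
}

#' Grow a focal input set to saturation and keep only input-input edges
#'
#' Repeatedly expands the current node set with the saturation shell
#' parameters (default: up to 50 first-shell interactors, no second shell),
#' feeding newly added nodes back in as seeds, until the node set reaches a
#' fixed point; then returns the subgraph induced on the ORIGINAL inputs,
#' i.e. only confidence-qualifying edges between inputs are retained.
#'
#' @param table Interaction tibble.
#' @param inputs Character vector of focal identifiers (non-empty).
#' @param config A [network_config()].
#' @return A `ppi_network` igraph on exactly the input nodes.
#' @export
grow_to_saturation <- function(table, inputs, config = network_config()) {
  assert_that(length(inputs) > 0, "inputs must be non-empty")
  inputs <- unique(as.character(inputs))
  current <- inputs
  repeat {
    res <- expand_core(table, current, config$min_confidence,
                       config$saturation_shell1, config$saturation_shell2)
    grown <- sort(unique(res$nodes$node))
    if (setequal(grown, current)) break
    current <- grown
  }
  edges <- canonical_edges(table) |>
    filter(.data$combined_score >= config$min_confidence,
           .data$protein1 %in% inputs, .data$protein2 %in% inputs)
  as_ppi_network(tibble(node = inputs, shell = 0L), edges)
}

#' Node and edge tables of a built network
#'
#' @param net A `ppi_network`.
#' @return `network_nodes()`: tibble `node`, `shell`, `is_seed`, `is_deg`,
#'   `direction`, `degree`; `network_edges()`: tibble `protein1`,
#'   `protein2`, `score`.
#' @export
network_nodes <- function(net) {
  tibble(
    node = igraph::V(net)$name,
    shell = igraph::V(net)$shell,
    is_seed = igraph::V(net)$is_seed,
    is_deg = igraph::V(net)$is_deg,
    direction = igraph::V(net)$direction,
    degree = as.integer(igraph::degree(net))
  )
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  if (igraph::ecount(net) == 0) {
    return(tibble(protein1 = character(), protein2 = character(),
                  score = numeric()))
  }
  ends <- igraph::as_edgelist(net)
  tibble(protein1 = pmin(ends[, 1], ends[, 2]),
         protein2 = pmax(ends[, 1], ends[, 2]),
         score = igraph::E(net)$score) |>
    arrange(.data$protein1, .data$protein2)
}

#' Write a network as SIF plus attribute TSVs
#'
#' @param net A `ppi_network`.
#' @param prefix Output path prefix; writes `<prefix>.sif` (tab-separated
#'   `node1 pp node2`, isolated nodes on single-field lines),
#'   `<prefix>_edges.tsv` and `<prefix>_nodes.tsv`.
#' @return Invisibly, the SIF path.
#' @export
write_network <- function(net, prefix) {
  edges <- network_edges(net)
  nodes <- network_nodes(net)
  sif <- file.path(paste0(prefix, ".sif"))
  lines <- sprintf("%s\tpp\t%s", edges$protein1, edges$protein2)
  isolated <- setdiff(nodes$node, unique(c(edges$protein1, edges$protein2)))
  writeLines(c(lines, isolated), sif)
  readr::write_tsv(edges, paste0(prefix, "_edges.tsv"))
  readr::write_tsv(nodes, paste0(prefix, "_nodes.tsv"))
  invisible(sif)
}

#' Read a SIF file into an edge tibble
#'
#' @param path SIF path (`node1<TAB>relation<TAB>node2`, one edge per line;
#'   single-field lines are isolated nodes).
#' @return A `ppi_network` igraph (unweighted; scores set to 1).
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  edges <- purrr::keep(parts, ~ length(.x) >= 3)
  singles <- purrr::keep(parts, ~ length(.x) == 1)
  e <- if (length(edges)) {
    tibble(protein1 = vapply(edges, `[[`, "", 1),
           protein2 = vapply(edges, `[[`, "", 3),
           combined_score = 1)
  } else {
    tibble(protein1 = character(), protein2 = character(),
           combined_score = numeric())
  }
  all_nodes <- unique(c(e$protein1, e$protein2,
                        vapply(singles, `[[`, "", 1)))
  as_ppi_network(tibble(node = all_nodes, shell = 0L), canonical_edges(e))
}
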