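#' Configuration for the synthetic-data generators
#'
#' Bundles every parameter of the three seeded generators: two-cohort log2
#' expression matrices with planted fold changes, a preferential-attachment
#' interaction network with a planted hub, and gene-set annotations with one
#' planted enriched term. All three generators draw gene identifiers from one
#' shared universe of `n_genes` symbols so downstream joins (expression to
#' network to annotation) are non-trivially non-empty, mirroring how a real
#' analysis lives in a single gene-symbol space.
#'
#' Defaults emulate the study conditions of a rectal-epithelium microarray
#' cohort (16 case vs 13 control samples); `n_case = 19, n_control = 9` gives
#' the bronchial-like design.
#'
#' @param seed Integer master seed. Each generator derives its own substream
#'   from it, so identical configs give byte-identical outputs.
#' @param n_genes Size of the shared gene universe.
#' @param n_case,n_control Samples per group.
#' @param n_planted_deg Number of genes given a true fold change.
#' @param effect_lfc Magnitude of the planted log2 fold change (sign is drawn
#'   per gene).
#' @param noise_sd Per-gene residual standard deviation on the log2 scale.
#'   A single positive number gives homoscedastic noise; a length-2 range
#'   draws per-gene sigma log-uniformly within it (heteroscedastic), which
#'   exercises the variance shrinkage of the moderated t.
#' @param baseline_mean,baseline_sd Normal law for the per-gene baseline log2
#'   intensity mu_g.
#' @param net_n_nodes,net_m_attach Preferential-attachment parameters: growth
#'   starts from a complete graph on `net_m_attach + 1` nodes and every new
#'   node attaches `net_m_attach` edges.
#' @param planted_hub_extra_links Extra edges wired from the planted hub to
#'   random non-neighbours.
#' @param score_beta_params Shape pair of the Beta law for edge confidence
#'   scores; the default Beta(2, 1) leaves ~16% of edges below the 0.4
#'   confidence filter so the filter is actually exercised.
#' @param n_terms Number of annotation terms.
#' @param term_size_range Inclusive range of term sizes (uniform draw).
#' @param planted_term_overlap How many members of the planted term are taken
#'   from the planted DEG list; defaults to 30 capped at `n_planted_deg`.
#'
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 1000L,
                             n_case = 16L,
                             n_control = 13L,
                             n_planted_deg = 50L,
                             effect_lfc = 2.0,
                             noise_sd = 0.5,
                             baseline_mean = 7,
                             baseline_sd = 1,
                             net_n_nodes = 200L,
                             net_m_attach = 2L,
                             planted_hub_extra_links = 30L,
                             score_beta_params = c(2, 1),
                             n_terms = 50L,
                             term_size_range = c(10L, 40L),
                             planted_term_overlap = NULL) {
  if (is.null(planted_term_overlap)) {
    planted_term_overlap <- min(30L, as.integer(n_planted_deg))
  }
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_planted_deg = as.integer(n_planted_deg), effect_lfc = effect_lfc,
    noise_sd = noise_sd, baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    net_n_nodes = as.integer(net_n_nodes), net_m_attach = as.integer(net_m_attach),
    planted_hub_extra_links = as.integer(planted_hub_extra_links),
    score_beta_params = score_beta_params, n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range),
    planted_term_overlap = as.integer(planted_term_overlap)
  )
  counts <- c(cfg$n_genes, cfg$n_case, cfg$n_control, cfg$n_planted_deg,
              cfg$net_n_nodes, cfg$planted_hub_extra_links, cfg$n_terms,
              cfg$planted_term_overlap)
  assert_that(all(counts >= 0), "all counts must be >= 0")
  assert_that(cfg$n_planted_deg <= cfg$n_genes,
              "n_planted_deg must not exceed n_genes")
  assert_that(cfg$planted_term_overlap <= cfg$n_planted_deg,
              "planted_term_overlap must not exceed n_planted_deg")
  assert_that(all(is.finite(cfg$noise_sd)) && all(cfg$noise_sd > 0),
              "noise_sd must be positive")
  assert_that(length(cfg$noise_sd) %in% 1:2, "noise_sd is a scalar or a range")
  assert_that(cfg$net_n_nodes > cfg$net_m_attach && cfg$net_m_attach >= 1,
              "need net_n_nodes > net_m_attach >= 1")
  assert_that(length(cfg$score_beta_params) == 2 && all(cfg$score_beta_params > 0),
              "score_beta_params must be two positive shapes")
  assert_that(length(cfg$term_size_range) == 2 &&
                cfg$term_size_range[1] <= cfg$term_size_range[2],
              "term_size_range must be an increasing pair")
  structure(cfg, class = "synthetic_config")
}

gene_universe <- function(config) {
  sprintf("G%0*d", max(4, nchar(config$n_genes)), seq_len(config$n_genes))
}

#' Simulate a two-group log2 expression cohort with planted fold changes
#'
#' Entry for gene g, sample j is `mu_g + delta_g * [j is case] + eps_gj` with
#' `eps_gj ~ N(0, sigma_g^2)`; `delta_g = +/- effect_lfc` for the planted
#' genes (sign drawn once per gene), 0 otherwise. The generator emits
#' already-normalised log2 values: array-platform artifacts (probe-level
#' intensities, batch effects) are deliberately out of its scope.
#'
#' @param config A [synthetic_config()].
#' @param tissue_label Label folded into the random substream and into sample
#'   identifiers, so different tissues from the same master seed give
#'   independent cohorts.
#' @param planted Optional tibble with columns `gene` and `lfc` fixing the
#'   planted genes and their signed effects (used by [simulate_study()] to
#'   share planted genes between tissues); by default both are drawn.
#'
#' @return A list with `expression` (tibble: `gene` column then one column
#'   per sample), `samples` (tibble: `sample_id`, `group` in case/control) and
#'   `truth` (list with `planted_deg`, a tibble of gene and signed lfc).
#' @export
generate_expression <- function(config, tissue_label = "tissue", planted = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  n_samp <- config$n_case + config$n_control
  assert_that(n_samp >= 4, "need n_case + n_control >= 4")
  genes <- gene_universe(config)
  withr::with_seed(stream_seed(config$seed, "expression", tissue_label), {
    if (is.null(planted)) {
      ids <- sample(genes, config$n_planted_deg)
      planted <- tibble(
        gene = ids,
        lfc = sample(c(-1, 1), length(ids), replace = TRUE) * config$effect_lfc
      )
    }
    stopifnot(all(planted$gene %in% genes))
    mu <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
    sigma <- if (length(config$noise_sd) == 2) {
      exp(runif(config$n_genes, log(config$noise_sd[1]), log(config$noise_sd[2])))
    } else {
      rep(config$noise_sd, config$n_genes)
    }
    delta <- numeric(config$n_genes)
    delta[match(planted$gene, genes)] <- planted$lfc
    group <- rep(c("case", "control"), c(config$n_case, config$n_control))
    eps <- matrix(rnorm(config$n_genes * n_samp, sd = sigma),
                  nrow = config$n_genes)  # sigma recycles down columns
    values <- mu + outer(delta, as.numeric(group == "case")) + eps
  })
  sample_ids <- sprintf("%s_%s_%02d", tissue_label, group,
                        stats::ave(seq_len(n_samp), group, FUN = seq_along))
  expr <- as_tibble(as.data.frame(values))
  names(expr) <- sample_ids
  expr <- dplyr::bind_cols(tibble(gene = genes), expr)
  list(
    expression = expr,
    samples = tibble(sample_id = sample_ids, group = group),
    truth = list(planted_deg = planted)
  )
}

# Preferential-attachment edge list on integer node indices.
pa_edges <- function(n, m) {
  clique <- t(utils::combn(m + 1L, 2L))
  deg <- integer(n)
  deg[seq_len(m + 1L)] <- m
  new_from <- integer(0); new_to <- integer(0)
  if (n > m + 1L) {
    for (i in seq(m + 2L, n)) {
      existing <- seq_len(i - 1L)
      tgt <- sample(existing, m, prob = deg[existing])
      new_from <- c(new_from, rep(i, m)); new_to <- c(new_to, tgt)
      deg[tgt] <- deg[tgt] + 1L
      deg[i] <- m
    }
  }
  cbind(c(clique[, 1], new_from), c(clique[, 2], new_to))
}

#' Simulate a scored protein-interaction table with a planted hub
#'
#' Grows an undirected simple graph by preferential attachment (complete
#' graph on `net_m_attach + 1` nodes, then each new node attaches
#' `net_m_attach` edges with probability proportional to current degree), so
#' the degree distribution is heavy-tailed like a real interactome. One
#' designated hub — the first founder node, which already sits in the dense
#' core — receives `planted_hub_extra_links` additional edges to distinct
#' random non-neighbours. Each edge gets a confidence score drawn from
#' `Beta(score_beta_params)`, leaving a nonzero fraction below the usual 0.4
#' confidence filter. Node identifiers are drawn from the shared gene
#' universe.
#'
#' @param config A [synthetic_config()].
#' @param include_genes Genes guaranteed to be among the network's node ids
#'   (e.g. planted DEGs), so downstream seed expansion has anchors; placed
#'   on uniformly random nodes.
#' @param core_genes Genes assigned to the highest-degree nodes of the grown
#'   graph (hub first, then descending degree, shuffled within the core).
#'   [simulate_study()] places the planted DEGs here, emulating the premise
#'   that a disease-associated expression module occupies a central,
#'   densely connected interactome neighbourhood — the structure the
#'   centrality stage is designed to recover.
#'
#' @return A list with `interactions` (tibble: `protein1`, `protein2`,
#'   `combined_score`) and `truth` (list with `planted_hub`).
#' @export
generate_interactions <- function(config, include_genes = character(),
                                  core_genes = character()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$net_n_nodes
  m <- config$net_m_attach
  include_genes <- setdiff(include_genes, core_genes)
  assert_that(length(include_genes) + length(core_genes) <= n,
              "include_genes/core_genes exceed net_n_nodes")
  withr::with_seed(stream_seed(config$seed, "interactions"), {
    ends <- pa_edges(n, m)
    # planted hub = the highest-degree node of the grown graph, so the extra
    # links guarantee strict degree dominance (others gain at most one edge)
    hub <- which.max(tabulate(as.vector(ends), nbins = n))
    if (config$planted_hub_extra_links > 0) {
      nb <- unique(c(ends[ends[, 1] == hub, 2], ends[ends[, 2] == hub, 1]))
      candidates <- setdiff(seq_len(n), c(hub, nb))
      assert_that(length(candidates) >= config$planted_hub_extra_links,
                  "planted_hub_extra_links exceeds available non-neighbours")
      extra <- sample(candidates, config$planted_hub_extra_links)
      ends <- rbind(ends, cbind(hub, extra))
    }
    # map node indices to gene symbols: core genes occupy the hub and the
    # other highest-degree nodes; other forced genes land on random indices
    universe <- gene_universe(config)
    others <- setdiff(universe, c(core_genes, include_genes))
    filler <- sample(others, n - length(core_genes) - length(include_genes))
    tail_pool <- sample(c(include_genes, filler))
    deg_now <- tabulate(as.vector(ends), nbins = n)
    rank_idx <- order(-deg_now, seq_len(n))  # hub (index 1) ranks first
    rank_idx <- c(hub, setdiff(rank_idx, hub))
    ids <- character(n)
    ids[rank_idx[seq_along(core_genes)]] <- sample(core_genes)
    ids[rank_idx[length(core_genes) + seq_along(tail_pool)]] <- tail_pool
    scores <- rbeta(nrow(ends), config$score_beta_params[1],
                    config$score_beta_params[2])
  })
  a <- ids[ends[, 1]]; b <- ids[ends[, 2]]
  tbl <- tibble(
    protein1 = pmin(a, b), protein2 = pmax(a, b),
    combined_score = scores
  ) |> arrange(.data$protein1, .data$protein2)
  list(interactions = tbl, truth = list(planted_hub = ids[hub]))
}

#' Simulate gene-set annotations with one planted enriched term
#'
#' Draws `n_terms` gene sets with sizes uniform in `term_size_range` from the
#' shared gene universe. The first term is the planted one: it contains
#' `planted_term_overlap` genes taken from the supplied planted DEG list,
#' topped up with random non-planted fillers to the upper size bound, so a
#' correct over-representation analysis must flag it.
#'
#' @param config A [synthetic_config()].
#' @param truth Planted DEG identifiers: either a character vector or the
#'   `truth` element returned by [generate_expression()].
#' @param planted_core Optional explicit choice of the planted term's core
#'   genes (a subset of `truth` of length `planted_term_overlap`); by
#'   default the core is sampled uniformly from the planted DEG list.
#'   [simulate_study()] passes the most-connected planted genes here so the
#'   planted pathway occupies the module's network core.
#'
#' @return An annotation tibble (`term`, `description`, list-column
#'   `members`) with attribute `planted_term` naming the planted term id.
#' @export
generate_annotations <- function(config, truth, planted_core = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  planted_ids <- if (is.character(truth)) truth else truth$planted_deg$gene
  assert_that(config$term_size_range[1] >= 2,
              "term_size_range lower bound must be >= 2")
  assert_that(length(planted_ids) >= config$planted_term_overlap,
              "not enough planted DEG ids for planted_term_overlap")
  universe <- gene_universe(config)
  if (config$n_terms == 0) {
    out <- tibble(term = character(), description = character(),
                  members = list())
    attr(out, "planted_term") <- NA_character_
    return(out)
  }
  withr::with_seed(stream_seed(config$seed, "annotations"), {
    sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                    config$n_terms, replace = TRUE)
    terms <- sprintf("T%03d", seq_len(config$n_terms))
    members <- lapply(sizes, function(s) sort(sample(universe, s)))
    core <- if (is.null(planted_core)) {
      sample(planted_ids, config$planted_term_overlap)
    } else {
      stopifnot(all(planted_core %in% planted_ids),
                length(planted_core) == config$planted_term_overlap)
      planted_core
    }
    filler_n <- max(config$term_size_range[2], config$planted_term_overlap) -
      config$planted_term_overlap
    fillers <- sample(setdiff(universe, planted_ids), filler_n)
    members[[1]] <- sort(c(core, fillers))
  })
  out <- tibble(
    term = terms,
    description = ifelse(terms == terms[1], "planted enriched term",
                         "random background term"),
    members = members
  )
  attr(out, "planted_term") <- terms[1]
  out
}

#' Simulate a full two-tissue study
#'
#' Coordinates the three generators into one consistent study: two expression
#' cohorts over a shared gene universe whose planted DEG sets overlap in
#' exactly `n_shared_planted` genes (with consistent signs, so shared genes
#' are shared in direction too), a single scored interaction table that
#' contains every planted DEG among its nodes, and one annotation set whose
#' planted term draws from the union of planted DEGs.
#'
#' @param config A [synthetic_config()]; its `n_case`/`n_control` apply to
#'   the first tissue.
#' @param tissue_labels Two labels.
#' @param n_case,n_control Length-2 cohort sizes; defaults are the
#'   rectal-like (16/13) and bronchial-like (19/9) designs.
#' @param n_shared_planted Planted DEGs common to both tissues.
#'
#' @return A list with `tissues` (named list of generate_expression outputs),
#'   `interactions`, `annotations` and `truth` (planted sets per tissue, the
#'   shared planted genes, planted hub and planted term).
#' @export
simulate_study <- function(config,
                           tissue_labels = c("rectal", "bronchial"),
                           n_case = c(16L, 19L),
                           n_control = c(13L, 9L),
                           n_shared_planted = 10L) {
  stopifnot(inherits(config, "synthetic_config"), length(tissue_labels) == 2)
  assert_that(n_shared_planted <= config$n_planted_deg,
              "n_shared_planted must not exceed n_planted_deg")
  assert_that(2 * config$n_planted_deg - n_shared_planted <= config$n_genes,
              "gene universe too small for the requested planted sets")
  genes <- gene_universe(config)
  withr::with_seed(stream_seed(config$seed, "study"), {
    shuffled <- sample(genes)
    a_ids <- shuffled[seq_len(config$n_planted_deg)]
    shared <- a_ids[seq_len(n_shared_planted)]
    fresh <- shuffled[config$n_planted_deg +
                        seq_len(config$n_planted_deg - n_shared_planted)]
    b_ids <- c(shared, fresh)
    all_ids <- union(a_ids, b_ids)
    signs <- sample(c(-1, 1), length(all_ids), replace = TRUE)
  })
  lfc_of <- function(ids) tibble(
    gene = ids, lfc = signs[match(ids, all_ids)] * config$effect_lfc
  )
  tissues <- list()
  for (i in 1:2) {
    cfg_i <- config
    cfg_i$n_case <- as.integer(n_case[i])
    cfg_i$n_control <- as.integer(n_control[i])
    tissues[[tissue_labels[i]]] <- generate_expression(
      cfg_i, tissue_label = tissue_labels[i],
      planted = lfc_of(if (i == 1) a_ids else b_ids)
    )
  }
  net <- generate_interactions(config, core_genes = all_ids)
  # the planted pathway occupies the most-connected planted genes, the
  # coupling between network centrality and functional coherence the
  # downstream HBS enrichment is designed to detect
  deg_count <- table(c(net$interactions$protein1, net$interactions$protein2))
  net_degree <- as.integer(deg_count[all_ids])
  net_degree[is.na(net_degree)] <- 0L
  core <- all_ids[order(-net_degree, all_ids)][
    seq_len(min(config$planted_term_overlap, length(all_ids)))]
  annot <- generate_annotations(config, truth = all_ids, planted_core = core)
  list(
    tissues = tissues,
    interactions = net$interactions,
    annotations = annot,
    truth = list(
      planted_deg = stats::setNames(
        list(lfc_of(a_ids), lfc_of(b_ids)), tissue_labels),
      shared_planted = shared,
      planted_hub = net$truth$planted_hub,
      planted_term = attr(annot, "planted_term")
    )
  )
}

#' Write synthetic-study inputs to disk
#'
#' Emits the on-disk forms the pipeline reads: per-tissue expression TSV
#' (first column `gene`) and sample sheet TSV, a shared interaction TSV
#' (`protein1`, `protein2`, `combined_score`), a GMT annotation file and a
#' ground-truth JSON.
#'
#' @param study Output of [simulate_study()].
#' @param outdir Directory (created if absent).
#' @return Invisibly, a named list of written paths.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (lab in names(study$tissues)) {
    t <- study$tissues[[lab]]
    paths[[paste0(lab, "_expression")]] <-
      file.path(outdir, paste0(lab, "_expression.tsv"))
    readr::write_tsv(t$expression, paths[[paste0(lab, "_expression")]])
    paths[[paste0(lab, "_samples")]] <-
      file.path(outdir, paste0(lab, "_samples.tsv"))
    readr::write_tsv(t$samples, paths[[paste0(lab, "_samples")]])
  }
  paths$interactions <- file.path(outdir, "interactions.tsv")
  readr::write_tsv(study$interactions, paths$interactions)
  paths$annotations <- file.path(outdir, "annotations.gmt")
  write_gmt(study$annotations, paths$annotations)
  paths$truth <- file.path(outdir, "truth.json")
  truth <- study$truth
  jsonlite::write_json(
    list(
      planted_deg = lapply(truth$planted_deg, function(x)
        list(gene = x$gene, lfc = x$lfc)),
      shared_planted = truth$shared_planted,
      planted_hub = truth$planted_hub,
      planted_term = truth$planted_term
    ),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
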