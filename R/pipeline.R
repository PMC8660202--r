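# End-to-end orchestration: per-tissue DEG calling, merged PPI network,
# HBS centrality, two-tier enrichment; cross-tissue overlap statistics; and
# the optional grow-to-saturation network around a focal gene.

#' Load and normalise a pipeline configuration
#'
#' Accepts a flat key-value YAML file or a named list. Two modes exist:
#' `mode: simulate` generates a full two-tissue synthetic study from the
#' seed and the synthetic parameters; `mode: files` reads the per-tissue
#' expression/sample TSVs plus the shared interaction TSV and GMT named in
#' the config. Unspecified keys take the package defaults.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A `pipeline_config` list with every threshold filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    assert_that(file.exists(config), sprintf("config file '%s' not found",
                                             config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    mode = "simulate", seed = 1L, outdir = NULL,
    tissue_a = "rectal", tissue_b = "bronchial",
    # synthetic study
    n_genes = 1000L, n_case_a = 16L, n_control_a = 13L,
    n_case_b = 19L, n_control_b = 9L,
    n_planted_deg = 50L, n_shared_planted = 10L,
    effect_lfc = 2.0, noise_sd = 0.5,
    net_n_nodes = 200L, net_m_attach = 2L, planted_hub_extra_links = 30L,
    n_terms = 50L, planted_term_overlap = 30L,
    # file mode inputs
    expression_a = NULL, samples_a = NULL,
    expression_b = NULL, samples_b = NULL,
    interactions = NULL, gmt = NULL,
    # stage thresholds
    lfc_cut = 0.5, fdr_cut = 0.05,
    min_confidence = 0.4, shell1_max = 20L, shell2_max = 5L,
    saturation_shell1 = 50L, saturation_shell2 = 0L,
    fdr_cut_deg = 0.05, fdr_cut_hbs = 0.001,
    min_term_size = 3L, max_term_size = 2000L,
    # optional focal gene for the saturation network
    focal_gene = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  assert_that(cfg$mode %in% c("simulate", "files"),
              "mode must be 'simulate' or 'files'")
  if (cfg$mode == "files") {
    need <- c("expression_a", "samples_a", "expression_b", "samples_b",
              "interactions", "gmt")
    missing <- need[vapply(cfg[need], is.null, logical(1))]
    assert_that(length(missing) == 0,
                paste("file mode needs keys:", paste(missing, collapse = ", ")))
    absent <- unlist(cfg[need])[!file.exists(unlist(cfg[need]))]
    assert_that(length(absent) == 0,
                paste("input file(s) not found:", paste(absent, collapse = ", ")))
  }
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

analyse_tissue <- function(label, expr, samples, interactions, annot,
                           universe, cfg, net_cfg, enr_cfg) {
  degs <- run_stage(paste0("deg:", label), {
    stats <- fit_group_stats(expr, samples)
    call_degs(stats, lfc_cut = cfg$lfc_cut, fdr_cut = cfg$fdr_cut)
  })
  net <- run_stage(paste0("network:", label), {
    if (attr(degs, "n_total_deg") == 0) {
      abort("no differentially expressed genes to seed the network")
    }
    build_merged_network(interactions, degs, net_cfg)
  })
  report <- run_stage(paste0("centrality:", label), {
    if (igraph::ecount(net) == 0) {
      mutate(tibble(node = igraph::V(net)$name, degree = 0L,
                    betweenness = 0, eigenvector = NA_real_),
             hub = FALSE, bottleneck = FALSE, switch = FALSE, hbs = FALSE)
    } else {
      classify_hbs(centrality_report(net))
    }
  })
  hbs <- report$node[report$hbs]
  enr_deg <- run_stage(paste0("enrichment-deg:", label), {
    enrich(degs$gene[degs$status != "ns"], annot, universe, enr_cfg,
           tier = "deg")
  })
  enr_hbs <- run_stage(paste0("enrichment-hbs:", label), {
    if (length(intersect(hbs, unlist(annot$members))) == 0) NULL else
      enrich(hbs, annot, universe, enr_cfg, tier = "hbs")
  })
  list(label = label, degs = degs, network = net, centrality = report,
       hbs = hbs, enrichment_deg = enr_deg, enrichment_hbs = enr_hbs)
}

sig_terms <- function(enr) if (is.null(enr)) character(0) else
  enr$term[enr$significant]

#' Run the full two-tissue pipeline
#'
#' Per tissue: moderated-t DEG calling, merged PPI network construction,
#' HBS centrality classification, and over-representation analysis of the
#' DEG list (FDR tier 0.05) and of the HBS node list (FDR tier 0.001).
#' Cross-tissue: DEG Venn partitions with shared percentages, shared
#' significant terms per tier, shared HBS nodes, and the member overlap of
#' every shared term (a tissue's "predicted genes" for a term are its
#' network nodes, so non-DEG members count — the rule a Venn over predicted
#' genes needs). If a focal gene is configured (or, in simulate mode, the
#' planted hub by default), a grow-to-saturation network is built around the
#' focal gene plus the union of HBS-DEGs.
#'
#' All artifacts are written under `outdir` together with a machine-readable
#' `summary.json` (versioned schema) and a `run.log` recording every
#' threshold and seed; the run is deterministic given config and seed.
#'
#' @param config A [pipeline_config()], a path to one, or a named list.
#' @param outdir Output directory (overrides the config's `outdir`; a
#'   temporary directory is used if neither is set).
#' @return Invisibly, a list with per-tissue results (`tissues`), the
#'   cross-tissue comparison (`overlap`, `shared_terms`, `shared_hbs`,
#'   `term_overlaps`), the optional `saturation` network, and `summary`
#'   (the JSON payload as a list).
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  outdir <- outdir %||% cfg$outdir %||% tempfile("fibronet_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message("[fibronet] ", line)
  }
  say("pipeline start: mode=%s seed=%d", cfg$mode, cfg$seed)
  say("thresholds: lfc_cut=%g fdr_cut=%g min_confidence=%g shell1=%d shell2=%d fdr_deg=%g fdr_hbs=%g",
      cfg$lfc_cut, cfg$fdr_cut, cfg$min_confidence, cfg$shell1_max,
      cfg$shell2_max, cfg$fdr_cut_deg, cfg$fdr_cut_hbs)

  labels <- c(cfg$tissue_a, cfg$tissue_b)
  truth <- NULL
  if (cfg$mode == "simulate") {
    syn <- run_stage("simulate", {
      synthetic_config(
        seed = cfg$seed, n_genes = cfg$n_genes,
        n_planted_deg = cfg$n_planted_deg, effect_lfc = cfg$effect_lfc,
        noise_sd = cfg$noise_sd, net_n_nodes = cfg$net_n_nodes,
        net_m_attach = cfg$net_m_attach,
        planted_hub_extra_links = cfg$planted_hub_extra_links,
        n_terms = cfg$n_terms, planted_term_overlap = cfg$planted_term_overlap
      )
    })
    study <- run_stage("simulate", {
      simulate_study(syn, tissue_labels = labels,
                     n_case = c(cfg$n_case_a, cfg$n_case_b),
                     n_control = c(cfg$n_control_a, cfg$n_control_b),
                     n_shared_planted = cfg$n_shared_planted)
    })
    write_study(study, file.path(outdir, "inputs"))
    tissues_in <- study$tissues
    interactions <- study$interactions
    annot <- study$annotations
    truth <- study$truth
    if (is.null(cfg$focal_gene)) cfg$focal_gene <- truth$planted_hub
  } else {
    tissues_in <- list(
      run_stage("read-expression", read_expression(cfg$expression_a,
                                                   cfg$samples_a)),
      run_stage("read-expression", read_expression(cfg$expression_b,
                                                   cfg$samples_b))
    )
    names(tissues_in) <- labels
    interactions <- run_stage("read-interactions",
                              read_interaction_table(cfg$interactions))
    annot <- run_stage("read-gmt", read_gmt(cfg$gmt))
  }

  net_cfg <- network_config(cfg$min_confidence, cfg$shell1_max,
                            cfg$shell2_max, cfg$saturation_shell1,
                            cfg$saturation_shell2)
  enr_cfg <- enrichment_config(cfg$fdr_cut_deg, cfg$fdr_cut_hbs,
                               cfg$min_term_size, cfg$max_term_size)

  tissues <- purrr::map(labels, function(lab) {
    t_in <- tissues_in[[lab]]
    universe <- t_in$expression[[1]]
    res <- analyse_tissue(lab, t_in$expression, t_in$samples, interactions,
                          annot, universe, cfg, net_cfg, enr_cfg)
    say("%s: %d over / %d under; network %d nodes / %d edges; %d HBS",
        lab, attr(res$degs, "n_over"), attr(res$degs, "n_under"),
        igraph::vcount(res$network), igraph::ecount(res$network),
        length(res$hbs))
    dir.create(file.path(outdir, lab), showWarnings = FALSE)
    write_deg_table(res$degs, file.path(outdir, lab, "deg_table.tsv"),
                    file.path(outdir, lab, "volcano.tsv"))
    write_network(res$network, file.path(outdir, lab, "network"))
    write_centrality(res$centrality, file.path(outdir, lab, "centrality.tsv"),
                     file.path(outdir, lab, "hbs_ids.txt"))
    write_enrichment(res$enrichment_deg,
                     file.path(outdir, lab, "enrichment_deg.tsv"))
    if (!is.null(res$enrichment_hbs)) {
      write_enrichment(res$enrichment_hbs,
                       file.path(outdir, lab, "enrichment_hbs.tsv"))
    }
    res
  })
  names(tissues) <- labels
  a <- tissues[[1]]; b <- tissues[[2]]

  overlap <- run_stage("overlap", shared_percentages(a$degs, b$degs))
  shared_terms <- list(
    deg = sort(intersect(sig_terms(a$enrichment_deg),
                         sig_terms(b$enrichment_deg))),
    hbs = sort(intersect(sig_terms(a$enrichment_hbs),
                         sig_terms(b$enrichment_hbs)))
  )
  shared_hbs <- sort(intersect(a$hbs, b$hbs))
  nodes_by_tissue <- stats::setNames(
    list(igraph::V(a$network)$name, igraph::V(b$network)$name), labels)
  term_overlaps <- purrr::map(
    unique(c(shared_terms$deg, shared_terms$hbs)),
    function(tm) term_member_overlap(annot, tm, nodes_by_tissue,
                                     a$degs, b$degs)
  )
  names(term_overlaps) <- unique(c(shared_terms$deg, shared_terms$hbs))
  readr::write_tsv(select(as_tibble(overlap), -"shared_ids"),
                   file.path(outdir, "overlap_summary.tsv"))

  saturation <- NULL
  if (!is.null(cfg$focal_gene)) {
    hbs_degs <- union(intersect(a$hbs, a$degs$gene[a$degs$status != "ns"]),
                      intersect(b$hbs, b$degs$gene[b$degs$status != "ns"]))
    saturation <- run_stage("saturation", {
      grow_to_saturation(interactions, union(cfg$focal_gene, hbs_degs),
                         net_cfg)
    })
    write_network(saturation, file.path(outdir, "saturation_network"))
    say("saturation network around %s: %d nodes / %d edges", cfg$focal_gene,
        igraph::vcount(saturation), igraph::ecount(saturation))
  }

  ov <- as_tibble(overlap)
  tissue_summary <- function(t) list(
    n_over = attr(t$degs, "n_over"),
    n_under = attr(t$degs, "n_under"),
    n_nodes = igraph::vcount(t$network),
    n_edges = igraph::ecount(t$network),
    n_hbs = length(t$hbs),
    n_sig_terms_deg = length(sig_terms(t$enrichment_deg)),
    n_sig_terms_hbs = length(sig_terms(t$enrichment_hbs))
  )
  summary <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    thresholds = cfg[c("lfc_cut", "fdr_cut", "min_confidence", "shell1_max",
                       "shell2_max", "saturation_shell1", "fdr_cut_deg",
                       "fdr_cut_hbs", "min_term_size", "max_term_size")],
    tissues = stats::setNames(list(tissue_summary(a), tissue_summary(b)),
                              labels),
    cross_tissue = list(
      shared_over = ov$n_shared[ov$direction == "over"],
      shared_under = ov$n_shared[ov$direction == "under"],
      shared_total = ov$n_shared[ov$direction == "all"],
      pct_shared = stats::setNames(
        as.list(ov$display_pct_of_a), paste0("of_", labels[1], "_", ov$direction)),
      shared_terms = shared_terms,
      shared_hbs = shared_hbs
    )
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "list")
  writeLines(log_lines, file.path(outdir, "run.log"))
  say("pipeline done: %s", outdir)

  invisible(list(
    config = cfg, outdir = outdir, tissues = tissues, overlap = overlap,
    shared_terms = shared_terms, shared_hbs = shared_hbs,
    term_overlaps = term_overlaps, saturation = saturation, truth = truth,
    summary = summary
  ))
}
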