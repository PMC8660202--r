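test_that("expression generator honours the configured design and seed", {
  cfg <- synthetic_config(seed = 1, n_genes = 1000, n_case = 16,
                          n_control = 13, n_planted_deg = 50)
  ex <- generate_expression(cfg, "rectal")
  expect_equal(nrow(ex$expression), 1000)
  expect_equal(ncol(ex$expression) - 1, 29)
  expect_equal(nrow(ex$truth$planted_deg), 50)
  expect_setequal(ex$samples$group[1:16], "case")
  expect_true(all(ex$truth$planted_deg$gene %in% ex$expression$gene))
  expect_true(all(abs(ex$truth$planted_deg$lfc) == cfg$effect_lfc))

  # no planted effects => empty truth
  ex0 <- generate_expression(synthetic_config(seed = 1, n_planted_deg = 0),
                             "rectal")
  expect_equal(nrow(ex0$truth$planted_deg), 0)

  # same seed twice => identical output; different tissue => different draw
  ex7a <- generate_expression(synthetic_config(seed = 7), "t")
  ex7b <- generate_expression(synthetic_config(seed = 7), "t")
  expect_identical(ex7a, ex7b)
  ex7c <- generate_expression(synthetic_config(seed = 7), "other")
  expect_false(identical(ex7a$expression, ex7c$expression))
})

test_that("invalid expression configs are rejected", {
  expect_error(synthetic_config(noise_sd = 0), "positive")
  expect_error(synthetic_config(noise_sd = -1), "positive")
  expect_error(synthetic_config(n_planted_deg = 20, n_genes = 10), "n_genes")
  expect_error(synthetic_config(planted_term_overlap = 60, n_planted_deg = 50),
               "planted_term_overlap")
  expect_error(generate_expression(synthetic_config(n_case = 2, n_control = 1)),
               ">= 4")
})

test_that("preferential-attachment network has the forced edge count", {
  cfg <- synthetic_config(seed = 5, net_n_nodes = 200, net_m_attach = 2,
                          planted_hub_extra_links = 0)
  net <- generate_interactions(cfg)
  # complete graph on 3 nodes + 2 edges per each of the 197 added nodes
  expect_equal(nrow(net$interactions), 3 + 2 * 197)
  expect_true(all(net$interactions$combined_score > 0 &
                    net$interactions$combined_score < 1))
  expect_true(all(net$interactions$protein1 != net$interactions$protein2))
  expect_false(any(duplicated(
    paste(net$interactions$protein1, net$interactions$protein2))))
})

test_that("planted hub dominates the degree distribution across seeds", {
  for (seed in 1:20) {
    cfg <- synthetic_config(seed = seed)
    net <- generate_interactions(cfg)
    deg <- table(c(net$interactions$protein1, net$interactions$protein2))
    hub <- net$truth$planted_hub
    expect_gt(deg[[hub]], max(deg[names(deg) != hub]))
  }
})

test_that("interaction generator is deterministic and validates extras", {
  cfg <- synthetic_config(seed = 3)
  expect_identical(generate_interactions(cfg), generate_interactions(cfg))
  tiny <- synthetic_config(seed = 3, net_n_nodes = 10, net_m_attach = 2,
                           planted_hub_extra_links = 50)
  expect_error(generate_interactions(tiny), "non-neighbours")
})

test_that("annotation generator plants the configured overlap", {
  cfg <- synthetic_config(seed = 2, n_terms = 20, term_size_range = c(10, 40),
                          planted_term_overlap = 30)
  ex <- generate_expression(cfg, "t")
  ann <- generate_annotations(cfg, ex$truth)
  expect_equal(nrow(ann), 20)
  planted <- attr(ann, "planted_term")
  members <- ann$members[[match(planted, ann$term)]]
  expect_length(intersect(members, ex$truth$planted_deg$gene), 30)
  expect_true(all(lengths(ann$members) >= 10 & lengths(ann$members) <= 40))

  empty <- generate_annotations(
    synthetic_config(seed = 2, n_terms = 0, planted_term_overlap = 0,
                     n_planted_deg = 0), character(0))
  expect_equal(nrow(empty), 0)

  bad <- synthetic_config(seed = 2, term_size_range = c(1, 40))
  expect_error(generate_annotations(bad, ex$truth), "term_size_range")
})

test_that("GMT writing round-trips the annotation family exactly", {
  cfg <- synthetic_config(seed = 4, n_terms = 8)
  ann <- generate_annotations(cfg, generate_expression(cfg, "t")$truth)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, path)
  back <- read_gmt(path)
  expect_equal(back$term, ann$term)
  expect_equal(back$members, ann$members)
  expect_equal(back$description, ann$description)
})

test_that("simulate_study shares exactly the requested planted genes", {
  cfg <- synthetic_config(seed = 9)
  study <- simulate_study(cfg, n_shared_planted = 10)
  pa <- study$truth$planted_deg[[1]]
  pb <- study$truth$planted_deg[[2]]
  shared <- intersect(pa$gene, pb$gene)
  expect_length(shared, 10)
  expect_setequal(shared, study$truth$shared_planted)
  # shared genes carry the same signed effect in both tissues
  expect_equal(pa$lfc[match(shared, pa$gene)], pb$lfc[match(shared, pb$gene)])
  # every planted gene appears in the interaction network node set
  nodes <- unique(c(study$interactions$protein1, study$interactions$protein2))
  expect_true(all(union(pa$gene, pb$gene) %in% nodes))
  expect_identical(study, simulate_study(synthetic_config(seed = 9),
                                         n_shared_planted = 10))
})

test_that("study writer emits all pipeline input files", {
  study <- simulate_study(synthetic_config(seed = 1, n_genes = 100,
                                           n_planted_deg = 10,
                                           planted_term_overlap = 5,
                                           net_n_nodes = 40,
                                           planted_hub_extra_links = 10))
  dir <- withr::local_tempdir()
  paths <- write_study(study, dir)
  expect_true(all(file.exists(unlist(paths))))
  back <- read_interaction_table(paths$interactions)
  expect_equal(nrow(back), nrow(study$interactions))
})
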