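test_that("interaction tables are scaled, deduplicated and channel-combined", {
  dir <- withr::local_tempdir()
  # STRING-style 0-1000 integer scores
  p1 <- file.path(dir, "a.tsv")
  readr::write_tsv(tibble::tibble(protein1 = "A", protein2 = "B",
                                  combined_score = 900), p1)
  expect_equal(read_interaction_table(p1)$combined_score, 0.9)

  # duplicate unordered pair keeps the max score
  p2 <- file.path(dir, "b.tsv")
  readr::write_tsv(tibble::tibble(protein1 = c("A", "B"),
                                  protein2 = c("B", "A"),
                                  combined_score = c(0.7, 0.9)), p2)
  tab <- read_interaction_table(p2)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$combined_score, 0.9)

  # per-channel scores combine as 1 - prod(1 - s)
  p3 <- file.path(dir, "c.tsv")
  readr::write_tsv(tibble::tibble(protein1 = "A", protein2 = "B",
                                  experiments = 0.5, databases = 0.5), p3)
  expect_equal(read_interaction_table(p3)$combined_score, 0.75)

  # bad rows are named
  p4 <- file.path(dir, "d.tsv")
  readr::write_tsv(tibble::tibble(protein1 = c("A", "C"),
                                  protein2 = c("B", "C"),
                                  combined_score = c(0.5, 0.5)), p4)
  expect_error(read_interaction_table(p4), "row 2")
})

test_that("seed expansion ranks, caps and confidence-filters interactors", {
  tab <- itable("A B 0.9; A C 0.8; A D 0.35; B C 0.7")
  net <- expand_seeds(tab, "A", network_config(shell1_max = 2, shell2_max = 0))
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))
  e <- network_edges(net)
  expect_setequal(paste(e$protein1, e$protein2), c("A B", "A C", "B C"))

  # zero shells: induced subgraph on the seeds alone
  net0 <- expand_seeds(tab, c("A", "B"),
                       network_config(shell1_max = 0, shell2_max = 0))
  expect_setequal(igraph::V(net0)$name, c("A", "B"))
  expect_equal(igraph::ecount(net0), 1)

  # no qualifying edges: isolated seeds survive
  neti <- expand_seeds(itable("X Y 0.2"), c("P", "Q"))
  expect_setequal(igraph::V(neti)$name, c("P", "Q"))
  expect_equal(igraph::ecount(neti), 0)

  # ranking: by max qualifying score desc, ties by ascending id
  tab2 <- itable("S A 0.5; S B 0.9; S C 0.5; S D 0.7")
  net2 <- expand_seeds(tab2, "S", network_config(shell1_max = 3,
                                                 shell2_max = 0))
  expect_setequal(igraph::V(net2)$name, c("S", "B", "D", "A"))
})

test_that("second shell is selected relative to seeds plus first shell", {
  tab <- itable("S A 0.9; A B 0.8; B C 0.9")
  net <- expand_seeds(tab, "S", network_config(shell1_max = 1,
                                               shell2_max = 1))
  expect_setequal(igraph::V(net)$name, c("S", "A", "B"))
  expect_equal(sort(igraph::V(net)$shell),
               c(0L, 1L, 2L))
})

test_that("iterative re-seeding merges unconnected inputs into one network", {
  tab <- itable("A B 0.9; X Y 0.9; B Y 0.5")
  degs <- deg_fixture(over = c("A", "X"))
  net <- build_merged_network(tab, degs)
  expect_setequal(igraph::V(net)$name, c("A", "B", "X", "Y"))
  expect_equal(igraph::count_components(net), 1)
  nodes <- network_nodes(net)
  expect_true(all(nodes$is_deg[nodes$node %in% c("A", "X")]))
  expect_equal(nodes$direction[nodes$node == "A"], "over")

  # an input with no qualifying edges anywhere stays isolated
  tab2 <- itable("A B 0.9")
  degs2 <- deg_fixture(over = c("A", "Z"))
  net2 <- build_merged_network(tab2, degs2)
  expect_true("Z" %in% igraph::V(net2)$name)
  expect_equal(igraph::degree(net2)[["Z"]], 0)

  # re-merging the result with itself changes nothing (idempotence)
  again <- build_merged_network(tab, degs)
  expect_equal(network_edges(again), network_edges(net))
  expect_equal(network_nodes(again), network_nodes(net))
})

test_that("merged network is independent of input ordering", {
  withr::with_seed(5, {
    cfg <- synthetic_config(seed = 5, n_genes = 120, n_planted_deg = 15,
                            planted_term_overlap = 10, net_n_nodes = 60)
    study <- simulate_study(cfg, n_shared_planted = 5)
    tab <- study$interactions
    degs <- deg_fixture(over = study$truth$planted_deg[[1]]$gene)
    net1 <- build_merged_network(tab, degs)
    net2 <- build_merged_network(tab, degs[sample(nrow(degs)), ])
    expect_equal(network_edges(net1), network_edges(net2))
    expect_equal(network_nodes(net1), network_nodes(net2))
  })
})

test_that("growth to saturation keeps only edges among the original inputs", {
  tab <- itable("A C 0.9; C B 0.9; A B 0.45")
  net <- grow_to_saturation(tab, c("A", "B"))
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  e <- network_edges(net)
  expect_equal(paste(e$protein1, e$protein2), "A B")

  # pairwise unconnected inputs give an edgeless network on the inputs
  net2 <- grow_to_saturation(itable("A C 0.9; B D 0.9"), c("A", "B"))
  expect_setequal(igraph::V(net2)$name, c("A", "B"))
  expect_equal(igraph::ecount(net2), 0)
})

test_that("confidence and shell monotonicity hold on synthetic tables", {
  cfg <- synthetic_config(seed = 8, n_genes = 150, n_planted_deg = 12,
                          planted_term_overlap = 8, net_n_nodes = 80)
  tab <- generate_interactions(cfg)$interactions
  seeds <- unique(c(tab$protein1[1:6], tab$protein2[1:4]))
  base <- expand_seeds(tab, seeds, network_config(min_confidence = 0.4))
  stricter <- expand_seeds(tab, seeds, network_config(min_confidence = 0.6))
  expect_true(all(igraph::V(stricter)$name %in% igraph::V(base)$name))
  expect_lte(igraph::ecount(stricter), igraph::ecount(base))

  wider <- expand_seeds(tab, seeds, network_config(shell1_max = 40,
                                                   shell2_max = 10))
  expect_true(all(igraph::V(base)$name %in% igraph::V(wider)$name))

  # every non-seed node imported has at least one qualifying edge
  nodes <- network_nodes(base)
  non_seed <- nodes$node[!nodes$is_seed]
  expect_true(all(nodes$degree[nodes$node %in% non_seed] >= 1))

  # every retained edge respects the confidence filter
  expect_true(all(network_edges(base)$score >= 0.4))
})

test_that("SIF round trip preserves the graph", {
  tab <- itable("A B 0.9; B C 0.7; D E 0.5")
  net <- expand_seeds(tab, c("A", "D", "Z"),
                      network_config(shell1_max = 20, shell2_max = 5))
  dir <- withr::local_tempdir()
  write_network(net, file.path(dir, "net"))
  back <- read_sif(file.path(dir, "net.sif"))
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(net))
})
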