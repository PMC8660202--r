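test_that("with no shrinkage the moderated t reduces to the pooled t-test", {
  # worked example: case (3,4,5) vs control (1,2,3)
  fx <- expr_fixture(list(g1 = list(case = c(3, 4, 5), control = c(1, 2, 3))))
  st <- fit_group_stats(fx$expression, fx$samples, d0_override = 0)
  expect_equal(st$log2FC, 2)
  expect_equal(st$s2, 1)
  expect_equal(st$df_resid, 4)
  expect_equal(st$t_mod, 2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st$t_mod, 2.449, tolerance = 1e-3)
  expect_equal(st$p_raw, 0.0705, tolerance = 1e-3)

  # oracle equivalence on random small matrices
  withr::with_seed(42, {
    for (rep in 1:5) {
      n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
      vals <- lapply(1:20, function(i)
        list(case = rnorm(n1), control = rnorm(n2)))
      names(vals) <- sprintf("g%02d", 1:20)
      fx <- expr_fixture(vals)
      st <- fit_group_stats(fx$expression, fx$samples, d0_override = 0)
      oracle <- vapply(vals, function(v) {
        tt <- t.test(v$case, v$control, var.equal = TRUE)
        c(tt$statistic, tt$p.value)
      }, numeric(2))
      expect_equal(st$t_mod, unname(oracle[1, ]), tolerance = 1e-10)
      expect_equal(st$p_raw, unname(oracle[2, ]), tolerance = 1e-10)
    }
  })
})

test_that("degenerate and limiting shrinkage cases behave as specified", {
  # identical values in both groups: zero effect, p = 1 even with d0 = 0
  fx <- expr_fixture(list(g1 = list(case = c(2, 2, 2), control = c(2, 2, 2))))
  st <- fit_group_stats(fx$expression, fx$samples, d0_override = 0)
  expect_equal(st$log2FC, 0)
  expect_equal(st$t_mod, 0)
  expect_equal(st$p_raw, 1)

  # constant but different: zero variance with nonzero effect is flagged
  fx2 <- expr_fixture(list(g1 = list(case = c(3, 3, 3), control = c(1, 1, 1))))
  st2 <- fit_group_stats(fx2$expression, fx2$samples, d0_override = 0)
  expect_equal(st2$flag, "zero_variance")
  expect_true(is.na(st2$p_raw))

  # infinite prior df: every gene uses the prior variance
  fx3 <- expr_fixture(list(
    a = list(case = c(1, 2, 3), control = c(0, 1, 2)),
    b = list(case = c(5, 1, 3), control = c(4, 0, 2))))
  st3 <- fit_group_stats(fx3$expression, fx3$samples,
                         d0_override = Inf, s0_override = 1)
  expect_equal(st3$t_mod, st3$log2FC / sqrt(1 * (1 / 3 + 1 / 3)),
               tolerance = 1e-12)
})

test_that("moderated t matches limma given the same hyper-parameters", {
  skip_if_not_installed("limma")
  withr::with_seed(11, {
    n1 <- 6; n2 <- 5; n_genes <- 300
    # heteroscedastic so shrinkage is non-trivial
    sigma <- exp(runif(n_genes, log(0.2), log(1)))
    mat <- matrix(rnorm(n_genes * (n1 + n2), sd = sigma), nrow = n_genes)
    mat[1:30, 1:n1] <- mat[1:30, 1:n1] + 1.5
  })
  genes <- sprintf("g%03d", seq_len(n_genes))
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes),
                           tibble::as_tibble(as.data.frame(mat)))
  names(expr)[-1] <- sprintf("s%02d", seq_len(n1 + n2))
  samples <- tibble::tibble(sample_id = names(expr)[-1],
                            group = rep(c("case", "control"), c(n1, n2)))
  design <- cbind(intercept = 1, case = rep(c(1, 0), c(n1, n2)))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  st <- fit_group_stats(expr, samples, d0_override = fit$df.prior,
                        s0_override = fit$s2.prior)
  expect_equal(st$t_mod, unname(fit$t[, "case"]), tolerance = 1e-9)
  expect_equal(st$p_raw, unname(fit$p.value[, "case"]), tolerance = 1e-9)
  # the package's own moment-matching hyper-parameters land close to limma's
  st_own <- fit_group_stats(expr, samples)
  expect_equal(attr(st_own, "d0"), fit$df.prior, tolerance = 0.15)
  expect_equal(attr(st_own, "s0_2"), fit$s2.prior, tolerance = 0.15)
  expect_gt(cor(st_own$t_mod, unname(fit$t[, "case"])), 0.9999)
})

test_that("BH adjustment matches the step-up definition and is monotone", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(1, {
    for (rep in 1:20) {
      p <- runif(sample(1:50, 1))
      q <- adjust_bh(p)
      expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
      # monotone: output order matches input p-value order
      expect_equal(order(q[order(p)]), seq_along(p))
      # permutation invariance
      perm <- sample(seq_along(p))
      expect_equal(adjust_bh(p[perm]), q[perm], tolerance = 1e-15)
    }
  })
})

test_that("DEG gates are strict on both fold change and FDR", {
  st <- tibble::tibble(
    gene = c("fold_fail", "fdr_fail", "under_hit", "over_hit", "edge"),
    log2FC = c(0.4, 0.7, -0.8, 0.8, 0.5),
    p_adj = c(0.001, 0.2, 0.01, 0.01, 0.01))
  d <- call_degs(st)
  expect_equal(d$status,
               c("ns", "ns", "under", "over", "ns"))  # |lfc| = cut is ns
  expect_equal(attr(d, "n_over"), 1L)
  expect_equal(attr(d, "n_under"), 1L)
  expect_equal(attr(d, "n_total_deg"), 2L)
})

test_that("null synthetic cohorts stay within the FDR budget", {
  rates <- vapply(1:20, function(seed) {
    cfg <- synthetic_config(seed = seed, n_planted_deg = 0)
    ex <- generate_expression(cfg, "null")
    d <- call_degs(fit_group_stats(ex$expression, ex$samples))
    attr(d, "n_total_deg") / nrow(d)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("planted effects are recovered with high sensitivity and low FDP", {
  ops <- vapply(1:10, function(seed) {
    cfg <- synthetic_config(seed = seed, n_case = 16, n_control = 13,
                            effect_lfc = 2, noise_sd = 0.5)
    ex <- generate_expression(cfg, "rectal")
    d <- call_degs(fit_group_stats(ex$expression, ex$samples))
    called <- d$gene[d$status != "ns"]
    truth <- ex$truth$planted_deg$gene
    c(sens = mean(truth %in% called),
      fdp = if (length(called)) mean(!called %in% truth) else 0)
  }, numeric(2))
  expect_gte(mean(ops["sens", ]), 0.90)
  expect_lte(mean(ops["fdp", ]), 0.10)
})

test_that("tidy and glance expose the fit as tibbles", {
  fx <- expr_fixture(list(a = list(case = c(1, 2, 3), control = c(0, 1, 2)),
                          b = list(case = c(2, 1, 2), control = c(2, 2, 1))))
  st <- fit_group_stats(fx$expression, fx$samples)
  expect_s3_class(tidy(st), "tbl_df")
  g <- glance(call_degs(st))
  expect_equal(g$n_genes, 2)
  expect_equal(g$n_case, 3)
  expect_false(is.na(g$n_over))
})
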