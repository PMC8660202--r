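# Empirical-Bayes moderated two-group differential expression.

# Moment-matching estimate of the scaled-inverse-chi-square prior on the
# per-gene variances. With z_g = log s2_g (finite values only), solve
#   trigamma(d0/2) = max(0, var(z) - trigamma(df/2))
# for d0 by monotone bisection on (0, 1e7]; a non-positive right-hand side
# means no excess dispersion beyond sampling noise, i.e. d0 = Inf (complete
# shrinkage). Then
#   log s0^2 = mean(z) - digamma(df/2) + log(df/2) + digamma(d0/2) - log(d0/2)
# with the d0 = Inf limit dropping the last two terms.
estimate_variance_prior <- function(s2, df) {
  z <- log(s2[is.finite(log(s2))])
  if (length(z) < 2) {
    return(list(d0 = Inf, s0_2 = if (length(z)) exp(mean(z)) else 1))
  }
  target <- max(0, var(z) - trigamma(df / 2))
  if (target <= 0 || target <= trigamma(1e7 / 2)) {
    d0 <- Inf
  } else {
    lo <- 1e-8; hi <- 1e7
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (trigamma(mid / 2) > target) lo <- mid else hi <- mid
      if (hi - lo < 1e-10 * max(1, lo)) break
    }
    d0 <- (lo + hi) / 2
  }
  log_s0 <- mean(z) - digamma(df / 2) + log(df / 2) +
    (if (is.finite(d0)) digamma(d0 / 2) - log(d0 / 2) else 0)
  list(d0 = d0, s0_2 = exp(log_s0))
}

#' Fit per-gene moderated two-group statistics
#'
#' Computes, for every gene, the log2 fold change (case minus control mean),
#' the pooled within-group variance, and the empirical-Bayes moderated
#' t-statistic: the per-gene variance is shrunk towards a prior variance
#' `s0^2` with prior degrees of freedom `d0`,
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`, and
#' `t_mod = log2FC / sqrt(s2_post * (1/n1 + 1/n2))` is referred to a Student
#' t with `d0 + df` degrees of freedom (normal limit when infinite). The
#' hyper-parameters are estimated from the observed spread of `log s2` by
#' closed-form moment matching unless `d0_override` pins them: `d0 = 0`
#' reduces exactly to the ordinary pooled-variance t-test, `d0 = Inf` uses
#' the common prior variance for every gene.
#'
#' @param expr Expression data frame: a `gene` identifier column followed by
#'   one numeric column per sample (log2 intensities), as written by
#'   [generate_expression()].
#' @param samples Sample sheet with columns `sample_id` and `group`
#'   (values `case` / `control`); both groups need >= 2 samples.
#' @param d0_override Optional prior degrees of freedom (>= 0 or `Inf`)
#'   bypassing estimation.
#' @param s0_override Optional prior variance, used with `d0_override`.
#'
#' @return A `gene_stats` tibble with columns `gene`, `log2FC`, `s2`,
#'   `df_resid`, `t_mod`, `p_raw`, `p_adj` (Benjamini-Hochberg) and `flag`
#'   (`"ok"` or `"zero_variance"` for genes where no sampling variability is
#'   available and the fold change is nonzero). Hyper-parameters attach as
#'   attributes `d0` and `s0_2`; retrieve them with [glance()].
#' @export
fit_group_stats <- function(expr, samples, d0_override = NULL,
                            s0_override = NULL) {
  stopifnot(is.data.frame(expr), is.data.frame(samples))
  assert_that(all(c("sample_id", "group") %in% names(samples)),
              "samples needs sample_id and group columns")
  assert_that(all(samples$group %in% c("case", "control")),
              "group labels must be 'case' or 'control'")
  gene_col <- names(expr)[1]
  genes <- as.character(expr[[gene_col]])
  assert_that(!anyDuplicated(genes), "duplicate gene ids")
  assert_that(all(samples$sample_id %in% names(expr)),
              "every sample_id must name an expression column")
  mat <- as.matrix(expr[, samples$sample_id, drop = FALSE])
  case <- mat[, samples$group == "case", drop = FALSE]
  ctrl <- mat[, samples$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  assert_that(n1 >= 2 && n2 >= 2, "each group needs >= 2 samples")

  lfc <- rowMeans(case) - rowMeans(ctrl)
  df <- n1 + n2 - 2
  s2 <- (rowSums((case - rowMeans(case))^2) +
           rowSums((ctrl - rowMeans(ctrl))^2)) / df

  if (is.null(d0_override)) {
    prior <- estimate_variance_prior(s2, df)
  } else {
    assert_that(d0_override >= 0, "d0_override must be >= 0 or Inf")
    prior <- list(d0 = d0_override,
                  s0_2 = s0_override %||% estimate_variance_prior(s2, df)$s0_2)
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2

  s2_post <- if (is.finite(d0)) (d0 * s0_2 + df * s2) / (d0 + df) else
    rep(s0_2, length(s2))
  se2 <- s2_post * (1 / n1 + 1 / n2)

  flag <- rep("ok", length(lfc))
  t_mod <- p_raw <- rep(NA_real_, length(lfc))
  zero <- se2 <= 0
  pos <- !zero
  df_total <- d0 + df
  t_mod[pos] <- lfc[pos] / sqrt(se2[pos])
  p_raw[pos] <- if (is.finite(df_total)) {
    2 * pt(-abs(t_mod[pos]), df_total)
  } else {
    2 * pnorm(-abs(t_mod[pos]))
  }
  # d0 = 0 with s2 = 0: no variance information at all
  t_mod[zero & lfc == 0] <- 0
  p_raw[zero & lfc == 0] <- 1
  flag[zero & lfc != 0] <- "zero_variance"

  out <- tibble(
    gene = genes, log2FC = lfc, s2 = s2, df_resid = df,
    t_mod = t_mod, p_raw = p_raw, p_adj = adjust_bh(p_raw), flag = flag
  )
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "n_case") <- n1
  attr(out, "n_control") <- n2
  class(out) <- c("gene_stats", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: sort p ascending,
#' `q_(i) = min over j >= i of min(1, p_(j) * m / j)`, returned in the
#' original order. `NA` entries pass through and do not count towards `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  assert_that(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes with fold-change and FDR gates
#'
#' A gene is `over` iff `log2FC > lfc_cut` and `p_adj < fdr_cut`, `under` iff
#' `log2FC < -lfc_cut` and `p_adj < fdr_cut`, otherwise `ns`. Both
#' inequalities are strict.
#'
#' @param stats A `gene_stats` tibble from [fit_group_stats()].
#' @param lfc_cut Absolute log2-fold-change gate (default 0.5).
#' @param fdr_cut Adjusted-p gate (default 0.05).
#' @return A `deg_table` tibble: `stats` plus a `status` column; summary
#'   counts attach as attributes `n_over`, `n_under`, `n_total_deg` and the
#'   thresholds as `lfc_cut`, `fdr_cut`.
#' @export
call_degs <- function(stats, lfc_cut = 0.5, fdr_cut = 0.05) {
  stopifnot(is.data.frame(stats))
  assert_that(all(c("gene", "log2FC", "p_adj") %in% names(stats)),
              "stats must carry gene, log2FC and p_adj")
  status <- dplyr::case_when(
    !is.na(stats$p_adj) & stats$log2FC > lfc_cut & stats$p_adj < fdr_cut ~ "over",
    !is.na(stats$p_adj) & stats$log2FC < -lfc_cut & stats$p_adj < fdr_cut ~ "under",
    TRUE ~ "ns"
  )
  out <- mutate(as_tibble(stats), status = status)
  for (a in c("d0", "s0_2", "n_case", "n_control"))
    attr(out, a) <- attr(stats, a)
  attr(out, "lfc_cut") <- lfc_cut
  attr(out, "fdr_cut") <- fdr_cut
  attr(out, "n_over") <- sum(status == "over")
  attr(out, "n_under") <- sum(status == "under")
  attr(out, "n_total_deg") <- sum(status != "ns")
  class(out) <- c("deg_table", "gene_stats", setdiff(class(stats),
                                                     c("deg_table", "gene_stats")))
  out
}

#' @method tidy gene_stats
#' @export
tidy.gene_stats <- function(x, ...) {
  as_tibble(x)
}

#' @method glance gene_stats
#' @export
glance.gene_stats <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_case = attr(x, "n_case"),
    n_control = attr(x, "n_control"),
    d0 = attr(x, "d0"),
    s0_2 = attr(x, "s0_2"),
    n_over = attr(x, "n_over") %||% NA_integer_,
    n_under = attr(x, "n_under") %||% NA_integer_,
    lfc_cut = attr(x, "lfc_cut") %||% NA_real_,
    fdr_cut = attr(x, "fdr_cut") %||% NA_real_
  )
}

#' Read an expression matrix and sample sheet from TSV
#'
#' @param expr_path TSV whose first column is `gene`, remaining columns one
#'   per sample.
#' @param samples_path TSV with `sample_id` and `group` columns.
#' @return List with `expression` and `samples` tibbles.
#' @export
read_expression <- function(expr_path, samples_path) {
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  list(expression = expr, samples = samples)
}

#' Write a DEG table (and its volcano-ready companion) to TSV
#'
#' @param degs A `deg_table`.
#' @param path Output TSV path.
#' @param volcano_path Optional path for a volcano-plot-ready TSV
#'   (`gene`, `log2FC`, `neg_log10_p_adj`, `status`).
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(degs, path, volcano_path = NULL) {
  readr::write_tsv(select(as_tibble(degs), "gene", "log2FC", "t_mod",
                          "p_raw", "p_adj", "status"), path)
  if (!is.null(volcano_path)) {
    readr::write_tsv(
      tibble(gene = degs$gene, log2FC = degs$log2FC,
             neg_log10_p_adj = -log10(degs$p_adj), status = degs$status),
      volcano_path
    )
  }
  invisible(path)
}
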