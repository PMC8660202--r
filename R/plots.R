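# ggplot2 views of the main result types.

#' Volcano plot of a DEG table
#'
#' log2 fold change against -log10 adjusted p, coloured by call status, with
#' the fold-change and FDR gates drawn as reference lines.
#'
#' @param degs A `deg_table` from [call_degs()].
#' @param lfc_cut,fdr_cut Gate positions for the reference lines; default to
#'   the thresholds stored on the table.
#' @return A ggplot object.
#' @export
plot_volcano <- function(degs, lfc_cut = NULL, fdr_cut = NULL) {
  lfc_cut <- lfc_cut %||% attr(degs, "lfc_cut") %||% 0.5
  fdr_cut <- fdr_cut %||% attr(degs, "fdr_cut") %||% 0.05
  df <- as_tibble(degs) |> filter(!is.na(.data$p_adj))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2FC,
                                   y = -log10(.data$p_adj),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(fdr_cut), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(over = "#c0392b", under = "#27ae60", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 adjusted p", colour = "status") +
    ggplot2::theme_minimal()
}

#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, top_n = 15, ...) {
  df <- head(arrange(as_tibble(object), .data$p_adj), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_adj),
    y = stats::reorder(.data$term, -.data$p_adj),
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "fdr_cut")),
                        linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2980b9",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL,
                  fill = sprintf("FDR < %g", attr(object, "fdr_cut"))) +
    ggplot2::theme_minimal()
}

#' @method autoplot centrality_report
#' @export
autoplot.centrality_report <- function(object, ...) {
  df <- as_tibble(object)
  if (!"hbs" %in% names(df)) df$hbs <- FALSE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$betweenness,
                                   size = .data$eigenvector,
                                   colour = .data$hbs)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#8e44ad",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "degree", y = "betweenness (raw)",
                  size = "eigenvector", colour = "HBS") +
    ggplot2::theme_minimal()
}
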