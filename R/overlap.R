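# Cross-tissue comparison: Venn partitions, shared-gene percentages with the
# display truncation rule, and shared-term member overlap.

#' Partition two id sets into a Venn layout
#'
#' @param set_a,set_b Vectors of identifiers.
#' @return List with `only_a`, `shared`, `only_b` (sorted id vectors) and
#'   counts `n_only_a`, `n_shared`, `n_only_b`.
#' @export
venn_partition <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  shared <- sort(intersect(set_a, set_b))
  only_a <- sort(setdiff(set_a, set_b))
  only_b <- sort(setdiff(set_b, set_a))
  list(only_a = only_a, shared = shared, only_b = only_b,
       n_only_a = length(only_a), n_shared = length(shared),
       n_only_b = length(only_b))
}

#' Shared-gene percentages between two tissues' DEG tables
#'
#' For each direction (`over`, `under`, and `all` = any DEG), the genes with
#' that status are intersected between tissues, and the shared count is
#' expressed as a percentage of each tissue's count in that direction:
#' `100 * shared / denominator`. Percentages are reported both at full
#' precision (`pct_of_a`, `pct_of_b`) and in display form truncated —
#' floored, not rounded — to 2 significant figures (`display_pct_of_a`,
#' `display_pct_of_b`), the rule that reproduces printed values such as
#' 4.2% for 2/47 (where round-half-up would give 4.3% on 0.186-style
#' inputs). A zero denominator yields `NA`, never an error.
#'
#' @param deg_a,deg_b `deg_table`s from [call_degs()] (any data frame with
#'   `gene` and `status` works).
#' @return An `overlap_summary` tibble with one row per direction: counts
#'   `n_a`, `n_b`, `n_only_a`, `n_shared`, `n_only_b`, the percentage
#'   columns, and a list-column `shared_ids`.
#' @export
shared_percentages <- function(deg_a, deg_b) {
  stopifnot(all(c("gene", "status") %in% names(deg_a)),
            all(c("gene", "status") %in% names(deg_b)))
  sets <- function(d, dir) {
    if (dir == "all") d$gene[d$status != "ns"] else d$gene[d$status == dir]
  }
  pct <- function(shared, denom) {
    if (denom == 0) NA_real_ else 100 * shared / denom
  }
  rows <- purrr::map(c("over", "under", "all"), function(dir) {
    a <- sets(deg_a, dir); b <- sets(deg_b, dir)
    v <- venn_partition(a, b)
    tibble(
      direction = dir,
      n_a = length(a), n_b = length(b),
      n_only_a = v$n_only_a, n_shared = v$n_shared, n_only_b = v$n_only_b,
      pct_of_a = pct(v$n_shared, length(a)),
      pct_of_b = pct(v$n_shared, length(b)),
      shared_ids = list(v$shared)
    )
  })
  out <- bind_rows(rows) |>
    mutate(
      display_pct_of_a = format_sigfig(signif_floor(.data$pct_of_a)),
      display_pct_of_b = format_sigfig(signif_floor(.data$pct_of_b))
    )
  class(out) <- c("overlap_summary", class(out))
  out
}

#' Overlap of two tissues' predicted genes within one annotation term
#'
#' Restricts each tissue's predicted gene set to the members of `term_id`
#' and partitions the restrictions. Each shared gene is additionally flagged
#' by where (if anywhere) it is differentially expressed, supporting
#' statements of the form "shared members that show no differential
#' expression in either tissue".
#'
#' @param annot Annotation tibble.
#' @param term_id Term identifier (must exist in `annot`).
#' @param genes_by_tissue Named list of two id vectors — the genes predicted
#'   for each tissue (e.g. each tissue's network node set).
#' @param deg_a,deg_b Optional `deg_table`s used for the flags.
#' @return List with the Venn `partition` (within term members) and
#'   `shared_flags`, a tibble of `gene`, `deg_in_a`, `deg_in_b`, `flag`
#'   (`"a"`, `"b"`, `"both"`, `"neither"`).
#' @export
term_member_overlap <- function(annot, term_id, genes_by_tissue,
                                deg_a = NULL, deg_b = NULL) {
  assert_that(term_id %in% annot$term,
              sprintf("unknown term '%s'", term_id))
  assert_that(length(genes_by_tissue) == 2, "genes_by_tissue needs 2 tissues")
  members <- annot$members[[match(term_id, annot$term)]]
  part <- venn_partition(intersect(genes_by_tissue[[1]], members),
                         intersect(genes_by_tissue[[2]], members))
  deg_ids <- function(d) if (is.null(d)) character(0) else
    d$gene[d$status != "ns"]
  in_a <- part$shared %in% deg_ids(deg_a)
  in_b <- part$shared %in% deg_ids(deg_b)
  flags <- tibble(
    gene = part$shared, deg_in_a = in_a, deg_in_b = in_b,
    flag = dplyr::case_when(in_a & in_b ~ "both", in_a ~ "a", in_b ~ "b",
                            TRUE ~ "neither")
  )
  list(partition = part, shared_flags = flags)
}
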