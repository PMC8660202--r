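# Hypergeometric over-representation analysis with BH FDR at two stringency
# tiers: 0.05 for DEG lists, 0.001 for HBS network node lists. Gene sets are
# flat — no ontology-graph propagation or decorrelation.

#' Enrichment parameters
#'
#' @param fdr_cut_deg Adjusted-p cut for DEG-list queries (default 0.05).
#' @param fdr_cut_hbs Adjusted-p cut for HBS-list queries (default 0.001).
#' @param min_term_size,max_term_size Universe-restricted term-size window
#'   applied before testing.
#' @param universe_policy How the testing universe is formed from the caller
#'   supplied gene background: `"intersection"` (default) keeps genes present
#'   in both the background and the union of annotated genes,
#'   `"annotation"` uses the annotation union alone, `"explicit"` uses the
#'   background as given.
#' @return An `enrichment_config` list.
#' @export
enrichment_config <- function(fdr_cut_deg = 0.05, fdr_cut_hbs = 0.001,
                              min_term_size = 3L, max_term_size = 2000L,
                              universe_policy = c("intersection", "annotation",
                                                  "explicit")) {
  assert_that(fdr_cut_deg > 0 && fdr_cut_deg < 1 &&
                fdr_cut_hbs > 0 && fdr_cut_hbs < 1,
              "FDR cuts must lie in (0, 1)")
  assert_that(min_term_size <= max_term_size, "min_term_size > max_term_size")
  structure(list(fdr_cut_deg = fdr_cut_deg, fdr_cut_hbs = fdr_cut_hbs,
                 min_term_size = as.integer(min_term_size),
                 max_term_size = as.integer(max_term_size),
                 universe_policy = match.arg(universe_policy)),
            class = "enrichment_config")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then member identifiers. Duplicate members within a term collapse.
#'
#' @param path GMT path.
#' @return Annotation tibble: `term`, `description`, list-column `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(term = character(), description = character(),
                  members = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields",
                  short[1]))
  }
  tibble(
    term = vapply(parts, `[[`, "", 1),
    description = vapply(parts, `[[`, "", 2),
    members = lapply(parts, function(x) unique(x[-(1:2)]))
  )
}

#' Write an annotation set as GMT
#'
#' @param annot Annotation tibble (`term`, `description`, `members`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(annot, path) {
  lines <- vapply(seq_len(nrow(annot)), function(i) {
    paste(c(annot$term[i], annot$description[i], annot$members[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` when drawing `n` genes from a universe of `N` containing `K`
#' term members. Vectorised over `k`, `K`, `n`.
#'
#' @param k Observed hits in the query.
#' @param K Term size in the universe.
#' @param n Query size in the universe.
#' @param N Universe size.
#' @return Probabilities.
#' @export
hypergeometric_pvalue <- function(k, K, n, N) {
  assert_that(all(k >= 0) && all(k <= pmin(K, n)) && all(pmax(K, n) <= N),
              "need 0 <= k <= min(K, n) <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list against term sets
#'
#' One-sided hypergeometric (Fisher's exact upper tail) per term, with the
#' term size `K` restricted to the testing universe and the size window
#' applied before testing; Benjamini-Hochberg adjustment runs across exactly
#' the tested terms. Significance is strict: `p_adj < cut`, with the cut
#' picked by `tier` (`"deg"`: 0.05 tier for DEG lists; `"hbs"`: 0.001 tier
#' for HBS network lists, by default).
#'
#' @param query Character vector of gene ids (restricted to the universe
#'   before testing).
#' @param annot Annotation tibble from [read_gmt()] or
#'   [generate_annotations()].
#' @param universe Character vector of background gene ids (e.g. the genes
#'   of the expression matrix); transformed per the config's
#'   `universe_policy`.
#' @param config An [enrichment_config()].
#' @param tier `"deg"` or `"hbs"`.
#' @return An `enrichment_table` tibble: `term`, `description`, `k`, `K`,
#'   `n`, `N`, `p_raw`, `p_adj`, `significant`, list-column `hit_ids`;
#'   the tier, cut and universe size attach as attributes.
#' @export
enrich <- function(query, annot, universe, config = enrichment_config(),
                   tier = c("deg", "hbs")) {
  tier <- match.arg(tier)
  cut <- if (tier == "deg") config$fdr_cut_deg else config$fdr_cut_hbs
  annot_union <- unique(unlist(annot$members))
  universe <- unique(as.character(universe))
  universe <- switch(config$universe_policy,
    intersection = intersect(universe, annot_union),
    annotation = annot_union,
    explicit = universe
  )
  assert_that(length(universe) > 0, "empty universe after restriction")
  query <- intersect(unique(as.character(query)), universe)
  assert_that(length(query) > 0, "empty query after universe restriction")

  members_u <- lapply(annot$members, intersect, y = universe)
  K <- lengths(members_u)
  keep <- K >= config$min_term_size & K <= config$max_term_size
  hits <- lapply(members_u[keep], intersect, y = query)
  k <- lengths(hits)
  n <- length(query); N <- length(universe)
  p_raw <- if (any(keep)) hypergeometric_pvalue(k, K[keep], n, N) else numeric(0)
  p_adj <- adjust_bh(p_raw)
  out <- tibble(
    term = annot$term[keep],
    description = annot$description[keep],
    k = as.integer(k), K = as.integer(K[keep]),
    n = as.integer(n), N = as.integer(N),
    p_raw = p_raw, p_adj = p_adj,
    significant = p_adj < cut,
    hit_ids = hits
  ) |> arrange(.data$p_adj, .data$p_raw, .data$term)
  attr(out, "tier") <- tier
  attr(out, "fdr_cut") <- cut
  attr(out, "universe_size") <- N
  attr(out, "query_size") <- n
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Write an enrichment table to TSV
#'
#' @param table An `enrichment_table`.
#' @param path Output TSV path (hit ids join with `;`).
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(table, path) {
  flat <- mutate(as_tibble(table),
                 hit_ids = vapply(.data$hit_ids, paste, "", collapse = ";"))
  readr::write_tsv(flat, path)
  invisible(path)
}
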