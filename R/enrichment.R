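#' Filter a gene set to transcription factors
#'
#' Intersects a gene set with the genes annotated to a term — by default
#' GO:0003700 (DNA-binding transcription factor activity), the conventional
#' TF definition for marker screens.
#'
#' @param genes Character vector of gene ids.
#' @param annotation Long annotation tibble (`term_id`, `gene`, optionally
#'   `term_name`), e.g. from [read_gmt()] or [read_term_map()].
#' @param term Term id defining the filter set.
#' @return Sorted character vector of the genes annotated to `term`.
#' @export
tf_filter <- function(genes, annotation, term = "GO:0003700") {
  if (!term %in% annotation$term_id) abort(sprintf("term '%s' absent from annotation", term))
  term_genes <- annotation$gene[annotation$term_id == term]
  sort(intersect(unique(genes), term_genes))
}

#' Hypergeometric over-representation analysis
#'
#' Per term: after intersecting the term's genes with the background, the
#' overlap `k` of term and query is tested against the hypergeometric upper
#' tail P(X >= k) with `N` background genes, `K` term genes and `n` query
#' genes (equivalent to a one-sided Fisher exact test); p-values are BH
#' adjusted across tested terms. Terms with no background gene are skipped.
#'
#' @param query Gene set to test (must be a subset of `background`).
#' @param background Background gene universe — by convention all genes that
#'   entered the region-specificity analysis.
#' @param annotation Long annotation tibble (`term_id`, `gene`, optional
#'   `term_name`).
#' @param alpha Significance cutoff on the adjusted p (default 0.05).
#' @return Tibble sorted by adjusted p: `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p_value`, `adj_p`, `significant`.
#' @export
enrich <- function(query, background, annotation, alpha = 0.05) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(background) == 0) abort("empty background")
  extra <- setdiff(query, background)
  if (length(extra) > 0) {
    abort(paste0("query genes outside the background: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  ann <- annotation |>
    filter(.data$gene %in% background) |>
    distinct(.data$term_id, .data$gene)
  names_tbl <- if ("term_name" %in% names(annotation)) {
    distinct(annotation, .data$term_id, .data$term_name)
  } else {
    annotation |> distinct(.data$term_id) |> mutate(term_name = .data$term_id)
  }
  N <- length(background)
  n <- length(query)
  res <- ann |>
    group_by(.data$term_id) |>
    summarise(K = n(), k = sum(.data$gene %in% query), .groups = "drop") |>
    mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE)
    )
  res |>
    mutate(adj_p = bh_adjust(.data$p_value), significant = .data$adj_p < alpha) |>
    left_join(names_tbl, by = "term_id") |>
    select("term_id", "term_name", "k", "K", "n", "N", "p_value", "adj_p",
           "significant") |>
    arrange(.data$adj_p, .data$p_value, .data$term_id)
}
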