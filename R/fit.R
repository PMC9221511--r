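#' Fit the region-specificity analysis for one dataset
#'
#' Runs the whole single-species statistical path on a log2-scale expression
#' table: expression filtering, region means, SPM, per-gene one-way ANOVA
#' with BH adjustment, the permutation-null SPM threshold, and the final
#' specific-gene calls.
#'
#' @param x Log2-scale expression tibble (id column first).
#' @param metadata Sample metadata with `sample_id` and `region` (see
#'   [read_sample_metadata()]).
#' @param regions Region set for the specificity analysis.
#' @param merge Region merge rules applied before everything else.
#' @param expressed_threshold If non-`NULL`, genes must exceed this value in
#'   at least one design sample to enter the analysis (strict `>`).
#' @param alpha BH-adjusted p cutoff for calls (default 0.05).
#' @param percentile Percentile of the pooled permutation null defining tau.
#' @param seed Integer seed for the label permutations.
#' @return An object of class `spm_fit` with elements `spm`, `tests`,
#'   `null_dist`, `calls`, `region_means`, `design`, `expression`, `alpha`,
#'   `seed`. Use [tidy()] for the per-gene calls and [glance()] for a
#'   one-row summary.
#' @export
fit_region_specificity <- function(x, metadata,
                                   regions = c("LA", "V", "SA"),
                                   merge = c(LV = "V", RV = "V"),
                                   expressed_threshold = NULL,
                                   alpha = 0.05, percentile = 95, seed) {
  design <- region_design(metadata, regions = regions, merge = merge)
  keep_cols <- c(id_col_name(x), design$sample_id)
  missing_samples <- setdiff(design$sample_id, names(x))
  if (length(missing_samples) > 0) {
    abort(paste0("expression table lacks design samples: ",
                 paste(head(missing_samples, 5), collapse = ", ")))
  }
  xs <- x[, keep_cols]
  if (!is.null(expressed_threshold)) {
    xs <- filter_expressed(xs, expressed_threshold)
  }
  if (nrow(xs) == 0) abort("no genes pass the expression filter")
  rm_tbl <- region_means(xs, design)
  spm <- compute_spm(rm_tbl)
  excluded <- attr(spm, "excluded_genes")
  if (length(excluded) > 0) {
    xs <- xs[!xs[[1]] %in% excluded, , drop = FALSE]
    rm_tbl <- rm_tbl[!rm_tbl[[1]] %in% excluded, , drop = FALSE]
  }
  tests <- anova_per_gene(xs, design)
  null_dist <- permutation_null_threshold(xs, design, seed = seed,
                                          percentile = percentile)
  calls <- call_specific_genes(spm, tests, null_dist, alpha = alpha)
  structure(
    list(
      expression = xs,
      design = design,
      region_means = rm_tbl,
      spm = spm,
      tests = tests,
      null_dist = null_dist,
      calls = calls,
      alpha = alpha,
      seed = as.integer(seed)
    ),
    class = "spm_fit"
  )
}

#' @export
print.spm_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("Region-specificity fit: %d genes x %d samples, regions %s\n",
           "  tau = %.4f (p%g of permutation null), alpha = %g\n",
           "  %d specific gene-region calls\n"),
    g$n_genes, g$n_samples, paste(x$null_dist$regions, collapse = "/"),
    g$tau, x$null_dist$percentile, g$alpha, g$n_specific
  ))
  invisible(x)
}

#' Tidy the specific-gene calls of a fit
#'
#' @param x An `spm_fit`.
#' @param ... Unused.
#' @return The long calls tibble (`gene_id`, `region`, `spm`, `adj_p`, `tau`,
#'   `is_specific`, `multi_region`).
#' @export
tidy.spm_fit <- function(x, ...) {
  x$calls
}

#' One-row summary of a fit
#'
#' @param x An `spm_fit`.
#' @param ... Unused.
#' @return Tibble with gene/sample counts, tau, alpha, seed and the number of
#'   specific calls.
#' @export
glance.spm_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$spm),
    n_samples = nrow(x$design),
    n_regions = length(x$null_dist$regions),
    tau = x$null_dist$threshold,
    alpha = x$alpha,
    n_specific = sum(x$calls$is_specific),
    seed = x$seed
  )
}

#' Per-gene summary of specific regions
#'
#' Collapses the long calls table to one row per gene that is specific
#' somewhere, reporting the region of maximal SPM and whether several regions
#' qualified.
#'
#' @param fit An `spm_fit` or a calls tibble from [call_specific_genes()].
#' @return Tibble `gene_id`, `region`, `spm`, `adj_p`, `multi_region`.
#' @export
specific_gene_table <- function(fit) {
  calls <- if (inherits(fit, "spm_fit")) fit$calls else fit
  calls |>
    filter(.data$is_specific) |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$spm), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("gene_id", "region", "spm", "adj_p", "multi_region") |>
    arrange(.data$region, desc(.data$spm))
}
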