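#' Log2-transform a linear-scale expression table
#'
#' Replaces every intensity `v` by `log2(v + 1)`, the standard variance-taming
#' transform for array intensities and TPM values. Input must be on the linear
#' scale (all values >= 0).
#'
#' @param x Expression tibble: id column first, numeric sample columns.
#' @return A tibble of the same shape on the log2 scale.
#' @export
log2_transform <- function(x) {
  m <- expr_matrix(x)
  if (anyNA(m)) abort("missing values; run drop_incomplete_rows() first")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative intensity for gene '%s', sample '%s'",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  expr_tibble(log2(m + 1), id_col = id_col_name(x))
}

#' Add a pseudocount to every value
#'
#' @param x Expression tibble.
#' @param pseudocount Positive constant added to every element (default 1),
#'   used to avoid zeros before ratio-type statistics.
#' @return Shifted tibble.
#' @export
add_pseudocount <- function(x, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("pseudocount must be a single positive number")
  }
  m <- expr_matrix(x)
  expr_tibble(m + pseudocount, id_col = id_col_name(x))
}

#' Align per-sample medians
#'
#' Shifts each sample (additively, on the log2 scale) so that every sample's
#' median equals the grand median of the input per-sample medians. Rank order
#' within each sample is preserved.
#'
#' @param x Log2-scale expression tibble with >= 1 sample.
#' @return Median-aligned tibble.
#' @export
median_align <- function(x) {
  stop_if_empty(x, "expression matrix")
  m <- expr_matrix(x)
  if (anyNA(m)) abort("missing values; run drop_incomplete_rows() first")
  meds <- apply(m, 2, median)
  target <- median(meds)
  expr_tibble(sweep(m, 2, meds - target), id_col = id_col_name(x))
}

#' Percentile-normalize samples
#'
#' Shifts each sample (additively, on the log2 scale) so its q-th percentile
#' equals the grand median of the per-sample q-th percentiles. Percentiles use
#' linear interpolation between order statistics (quantile type 7). The
#' default q = 90 matches 90-percentile normalization of Agilent-style arrays.
#'
#' @param x Log2-scale expression tibble.
#' @param q Percentile in (0, 100); default 90.
#' @return Normalized tibble.
#' @export
percentile_normalize <- function(x, q = 90) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 100) {
    abort("q must be a single percentile in (0, 100)")
  }
  stop_if_empty(x, "expression matrix")
  m <- expr_matrix(x)
  if (anyNA(m)) abort("missing values; run drop_incomplete_rows() first")
  pq <- apply(m, 2, pctl, q = q)
  target <- median(pq)
  expr_tibble(sweep(m, 2, pq - target), id_col = id_col_name(x))
}

#' Drop rows containing missing values
#'
#' @param x Expression tibble (possibly with `NA` cells).
#' @return Tibble with incomplete rows removed; the number of removed rows is
#'   reported via a message and stored in attribute `n_removed`.
#' @export
drop_incomplete_rows <- function(x) {
  vals <- x[, -1, drop = FALSE]
  keep <- !rowSums(is.na(as.matrix(vals))) > 0
  n_removed <- sum(!keep)
  out <- x[keep, , drop = FALSE]
  if (n_removed > 0) inform(sprintf("drop_incomplete_rows: removed %d of %d rows", n_removed, nrow(x)))
  if (nrow(out) == 0) warn("all rows contained missing values; result is empty")
  attr(out, "n_removed") <- n_removed
  out
}

#' Collapse probes to genes by maximum signal
#'
#' Maps probe rows to genes with a probe map and keeps, for each gene and
#' sample, the maximum signal over that gene's probes. Probes absent from the
#' map are dropped (and counted).
#'
#' @param x Expression tibble keyed by probe id.
#' @param probe_map Tibble with columns `probe_id`, `gene_id`
#'   (see [read_probe_map()]).
#' @return Gene-level tibble (id column `gene_id`); attribute
#'   `n_unmapped` records dropped probes.
#' @export
collapse_probes <- function(x, probe_map) {
  if (nrow(probe_map) == 0) abort("empty probe map")
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    abort("probe_map needs columns probe_id and gene_id")
  }
  ids <- as.character(x[[1]])
  hit <- match(ids, probe_map$probe_id)
  n_unmapped <- sum(is.na(hit))
  if (n_unmapped > 0) {
    inform(sprintf("collapse_probes: dropped %d unmapped probes", n_unmapped))
  }
  keep <- !is.na(hit)
  m <- expr_matrix(x[keep, , drop = FALSE])
  gene <- probe_map$gene_id[hit[keep]]
  # element-wise max over each gene's probes
  genes <- sort(unique(gene))
  collapsed <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m),
                      dimnames = list(genes, colnames(m)))
  for (j in seq_len(ncol(m))) {
    collapsed[, j] <- vapply(split(m[, j], gene), max, numeric(1))[genes]
  }
  out <- expr_tibble(collapsed, id_col = "gene_id")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Filter to expressed genes
#'
#' Keeps genes whose value is strictly greater than `threshold` in at least
#' one sample. Platform-appropriate thresholds differ (e.g. low for log2 TPM,
#' higher for array intensities); the comparison is strict (`>`).
#'
#' @param x Expression tibble.
#' @param threshold Finite expression threshold.
#' @return Filtered tibble.
#' @export
filter_expressed <- function(x, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold)) {
    abort("threshold must be a single finite number (or -Inf for no filtering)")
  }
  m <- expr_matrix(x)
  keep <- apply(m, 1, function(v) any(v > threshold))
  x[keep, , drop = FALSE]
}

#' Floor expression values at zero
#'
#' Additive normalization shifts can push near-zero log2(x + 1)-scale values
#' slightly negative; the SPM statistic requires non-negative values, so
#' pipelines floor the normalized matrix at zero.
#'
#' @param x Expression tibble.
#' @return Tibble with every negative value replaced by 0.
#' @export
floor_at_zero <- function(x) {
  m <- expr_matrix(x)
  expr_tibble(pmax(m, 0), id_col = id_col_name(x))
}

#' Compute TPM from counts and gene lengths
#'
#' Transcripts per million: per sample, each gene's count is converted to a
#' per-kilobase rate and rescaled so the sample sums to 10^6.
#'
#' @param counts Count tibble: id column first, non-negative integer counts.
#' @param gene_lengths Tibble with columns `gene_id`, `length` (bp, > 0)
#'   covering every gene in `counts`.
#' @return Linear-scale TPM tibble; every column of a sample with any reads
#'   sums to 10^6. A sample with all-zero counts yields an all-zero column
#'   with a warning.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  m <- expr_matrix(counts)
  if (any(m < 0) || any(abs(m - round(m)) > 1e-8)) {
    abort("counts must be non-negative integers")
  }
  len <- gene_lengths$length[match(rownames(m), gene_lengths$gene_id)]
  if (anyNA(len)) abort("gene_lengths missing for some genes in counts")
  if (any(len <= 0)) abort("gene lengths must be strictly positive")
  rate <- m / (len / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warn(paste0("samples with all-zero counts: ",
                paste(colnames(m)[zero], collapse = ", ")))
    tot[zero] <- 1  # leaves those columns all-zero
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  expr_tibble(tpm, id_col = id_col_name(counts))
}
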