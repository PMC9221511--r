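#' Build a region design from sample metadata
#'
#' Maps each sample to one analysis region, applying merge rules first (the
#' default pools left and right ventricle into `V`), then restricting to the
#' declared region set. Samples whose merged region is outside `regions` are
#' dropped — they stay available for sample clustering but not for the
#' specificity statistics.
#'
#' @param metadata Tibble with at least `sample_id` and `region`.
#' @param regions Controlled region set used for specificity (default
#'   `c("LA", "V", "SA")`).
#' @param merge Named character vector of merge rules, `c(old = new)`;
#'   default `c(LV = "V", RV = "V")`.
#' @return Tibble (`sample_id`, `region`) with attribute `regions`; errors if
#'   any declared region ends up with zero samples.
#' @export
region_design <- function(metadata, regions = c("LA", "V", "SA"),
                          merge = c(LV = "V", RV = "V")) {
  if (length(regions) < 2) abort("need at least two regions")
  reg <- as.character(metadata$region)
  hit <- match(reg, names(merge))
  reg[!is.na(hit)] <- unname(merge[hit[!is.na(hit)]])
  d <- tibble(sample_id = as.character(metadata$sample_id), region = reg) |>
    filter(.data$region %in% regions)
  n_per <- table(factor(d$region, levels = regions))
  if (any(n_per == 0)) {
    abort(paste0("regions with zero samples: ",
                 paste(names(n_per)[n_per == 0], collapse = ", ")))
  }
  attr(d, "regions") <- regions
  d
}

design_regions <- function(design) {
  attr(design, "regions") %||% sort(unique(design$region))
}

# genes x regions mean matrix for the samples in `design`
region_mean_matrix <- function(m, design) {
  regions <- design_regions(design)
  missing_samples <- setdiff(design$sample_id, colnames(m))
  if (length(missing_samples) > 0) {
    abort(paste0("design samples absent from matrix: ",
                 paste(head(missing_samples, 5), collapse = ", ")))
  }
  unassigned <- setdiff(colnames(m), design$sample_id)
  if (length(unassigned) > 0) {
    abort(paste0("samples without a region assignment: ",
                 paste(head(unassigned, 5), collapse = ", "),
                 " (subset the matrix to the design samples first)"))
  }
  m <- m[, design$sample_id, drop = FALSE]
  g <- factor(design$region, levels = regions)
  ind <- stats::model.matrix(~ g - 1)
  means <- m %*% ind %*% diag(1 / as.vector(table(g)), nrow = length(regions))
  colnames(means) <- regions
  means
}

#' Per-gene region mean expression
#'
#' Arithmetic mean of each gene's expression over the samples of each region,
#' after merge rules (see [region_design()]).
#'
#' @param x Expression tibble whose sample columns are exactly the design's
#'   samples.
#' @param design Output of [region_design()].
#' @return Tibble `gene_id` + one mean column per region, in region order.
#' @export
region_means <- function(x, design) {
  m <- expr_matrix(x)
  expr_tibble(region_mean_matrix(m, design), id_col = id_col_name(x))
}

#' Compute the SPM specificity statistic
#'
#' For each gene, the SPM value of a region is the region's mean expression
#' divided by the Euclidean norm of the gene's region-mean vector: the cosine
#' between the mean vector and that region's axis. With non-negative means,
#' SPM lies in \[0, 1\] and the squared values sum to 1 per gene; SPM = 1
#' means expression confined to one region. Genes with an all-zero mean
#' vector have no defined direction and are excluded.
#'
#' @param rm Region-means tibble from [region_means()] (non-negative values).
#' @return Tibble `gene_id` + one SPM column per region; excluded genes are
#'   listed in attribute `excluded_genes`.
#' @export
compute_spm <- function(rm) {
  m <- expr_matrix(rm)
  if (any(m < 0)) abort("negative region means; SPM expects log2(x + 1)-scale data")
  norm <- sqrt(rowSums(m^2))
  excluded <- rownames(m)[norm == 0]
  if (length(excluded) > 0) {
    inform(sprintf("compute_spm: excluded %d genes with all-zero mean vectors",
                   length(excluded)))
  }
  keep <- norm > 0
  spm <- m[keep, , drop = FALSE] / norm[keep]
  out <- expr_tibble(spm, id_col = id_col_name(rm))
  attr(out, "excluded_genes") <- excluded
  out
}

#' One-way ANOVA across regions, per gene
#'
#' Fixed-effects one-way F test of region differences for every gene, with
#' Benjamini-Hochberg adjustment across genes. Computed by the sum-of-squares
#' decomposition (df k-1 and n-k) vectorized over genes. Degenerate genes
#' (zero total variance) get p = 1 and `degenerate = TRUE`; zero within-group
#' variance with unequal means gives F = Inf, p = 0.
#'
#' @inheritParams region_means
#' @return Tibble with `gene_id`, `f_statistic`, `p_value`, `adj_p`,
#'   `degenerate`.
#' @export
anova_per_gene <- function(x, design) {
  m <- expr_matrix(x)
  regions <- design_regions(design)
  if (length(regions) < 2) abort("need >= 2 regions to test")
  missing_samples <- setdiff(design$sample_id, colnames(m))
  if (length(missing_samples) > 0) {
    abort(paste0("design samples absent from matrix: ",
                 paste(head(missing_samples, 5), collapse = ", ")))
  }
  m <- m[, design$sample_id, drop = FALSE]
  n <- ncol(m)
  k <- length(regions)
  if (n <= k) abort("need more samples than regions")
  g <- factor(design$region, levels = regions)
  n_r <- as.vector(table(g))
  means <- region_mean_matrix(m, design)
  grand <- rowMeans(m)
  ssb <- as.vector((means - grand)^2 %*% n_r)
  sst <- rowSums((m - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  eps <- 1e-12
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  degenerate <- sst <= eps
  sep <- !degenerate & ssw <= eps  # perfect separation
  f[sep] <- Inf
  p[sep] <- 0
  f[degenerate] <- NA_real_
  p[degenerate] <- 1
  tibble(
    gene_id = rownames(m),
    f_statistic = unname(f),
    p_value = unname(p),
    adj_p = unname(bh_adjust(p)),
    degenerate = unname(degenerate)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Permutation null distribution of SPM and its threshold
#'
#' For each gene independently, draws one uniform random permutation of the
#' sample-to-region assignment (region multiplicities preserved), recomputes
#' region means and all region SPM values under the permuted labels, pools
#' every gene's null SPM values, and takes the `percentile`-th percentile as
#' the specificity threshold tau. Deterministic given `seed`.
#'
#' @inheritParams region_means
#' @param seed Integer seed (mandatory).
#' @param percentile Percentile of the pooled null defining tau (default 95).
#' @return Object of class `null_spm_distribution`: list with `null_spms`
#'   (length genes x regions, minus any gene whose permuted mean vector is
#'   all zero — such genes have no SPM direction and are excluded, as in
#'   [compute_spm()]), `threshold`, `percentile`, `seed`, `n_genes`,
#'   `regions`.
#' @export
permutation_null_threshold <- function(x, design, seed, percentile = 95) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    abort("an integer seed is required")
  }
  m <- expr_matrix(x)
  m <- m[, design$sample_id, drop = FALSE]
  n <- nrow(m)
  s <- ncol(m)
  perms <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) sample.int(s), integer(s))
  })
  # permuting a gene's labels == permuting its values under the fixed design
  mp <- matrix(m[cbind(rep(seq_len(n), each = s), as.vector(perms))],
               nrow = n, byrow = TRUE, dimnames = dimnames(m))
  means <- region_mean_matrix(mp, design)
  norm <- sqrt(rowSums(means^2))
  keep <- norm > 0
  null_spms <- as.vector(means[keep, , drop = FALSE] / norm[keep])
  structure(
    list(
      null_spms = null_spms,
      threshold = pctl(null_spms, percentile),
      percentile = percentile,
      seed = as.integer(seed),
      n_genes = n,
      regions = design_regions(design)
    ),
    class = "null_spm_distribution"
  )
}

#' @export
print.null_spm_distribution <- function(x, ...) {
  cat(sprintf(
    "Null SPM distribution: %d pooled values (%d genes x %d regions), tau = %.4f (p%g, seed %d)\n",
    length(x$null_spms), x$n_genes, length(x$regions), x$threshold,
    x$percentile, x$seed
  ))
  invisible(x)
}

#' Call region-specific genes
#'
#' A gene is specific for a region iff its SPM there exceeds the permutation
#' threshold tau and its BH-adjusted ANOVA p-value is below `alpha`. When tau
#' >= 1/sqrt(2) at most one region per gene can qualify; otherwise genes
#' qualifying in several regions are flagged (`multi_region`) and the region
#' of maximal SPM can be taken downstream.
#'
#' @param spm SPM tibble from [compute_spm()].
#' @param tests Tibble from [anova_per_gene()] (same gene universe).
#' @param null_dist A `null_spm_distribution` (or a bare numeric tau).
#' @param alpha Adjusted-p cutoff, default 0.05.
#' @return Long tibble: `gene_id`, `region`, `spm`, `adj_p`, `tau`,
#'   `is_specific`, `multi_region`.
#' @export
call_specific_genes <- function(spm, tests, null_dist, alpha = 0.05) {
  tau <- if (inherits(null_dist, "null_spm_distribution")) null_dist$threshold else null_dist
  id <- id_col_name(spm)
  miss1 <- setdiff(spm[[1]], tests$gene_id)
  miss2 <- setdiff(tests$gene_id, spm[[1]])
  if (length(miss1) > 0 || length(miss2) > 0) {
    abort("spm and tests must cover the same genes")
  }
  long <- spm |>
    pivot_longer(-all_of(id), names_to = "region", values_to = "spm") |>
    rename(gene_id = all_of(id)) |>
    left_join(tests[, c("gene_id", "adj_p")], by = "gene_id") |>
    mutate(tau = tau, is_specific = .data$spm > tau & .data$adj_p < alpha)
  long |>
    group_by(.data$gene_id) |>
    mutate(multi_region = sum(.data$is_specific) > 1) |>
    ungroup()
}

#' Z-score normalize SPM values per region
#'
#' Standardizes each region column to mean 0, sd 1 (denominator n - 1),
#' the form used for cross-platform SPM heatmaps. A zero-variance column
#' becomes all zeros with a warning.
#'
#' @param spm SPM tibble with >= 2 genes.
#' @return Tibble of z-scored SPM values, same shape.
#' @export
zscore_spm <- function(spm) {
  m <- expr_matrix(spm)
  if (nrow(m) < 2) abort("need >= 2 genes per region column")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  zero <- s == 0
  if (any(zero)) {
    warn(paste0("zero-variance SPM columns set to 0: ",
                paste(colnames(m)[zero], collapse = ", ")))
    s[zero] <- 1
  }
  z <- sweep(sweep(m, 2, mu), 2, s, "/")
  z[, zero] <- 0
  expr_tibble(z, id_col = id_col_name(spm))
}
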