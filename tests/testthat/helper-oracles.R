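# Independent oracles and small fixture builders used across the suite.

# Expression tibble from a numeric matrix with dimnames.
tbl_from_matrix <- function(m, id_col = "gene_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
}

rand_expr <- function(n_genes, sample_ids, seed, mean = 5, sd = 2) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * length(sample_ids), mean, sd),
                nrow = n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)), sample_ids))
    tbl_from_matrix(m)
  })
}

make_design <- function(regions, reps) {
  md <- tibble::tibble(
    sample_id = unlist(lapply(seq_along(regions), function(i) {
      sprintf("%s_%d", regions[i], seq_len(reps[i]))
    })),
    region = rep(regions, times = reps)
  )
  region_design(md, regions = regions, merge = character(0))
}

# Step-up BH oracle: explicit min over j >= i of min(1, p_(j) * m / j).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(vapply(i:m, function(j) min(1, (m / j) * ps[j]), numeric(1)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# One-way ANOVA oracle via R's model-fitting machinery.
oracle_anova <- function(values, groups) {
  s <- summary(stats::aov(values ~ factor(groups)))[[1]]
  list(f = s$`F value`[1], p = s$`Pr(>F)`[1])
}

# Exact hypergeometric upper tail P(X >= k) by combinatorial summation.
brute_hyper_tail <- function(k, K, n, N) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j) {
    choose(K, j) * choose(N - K, n - j) / choose(N, n)
  }, numeric(1)))
}

# Brute-force UPGMA agglomeration; returns the cophenetic distance matrix,
# which identifies the average-linkage tree.
brute_upgma_coph <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  labels <- rownames(dm)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  members <- as.list(seq_len(n))
  while (length(members) > 1) {
    k <- length(members)
    best <- Inf; bi <- NA; bj <- NA
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        dij <- mean(dm[members[[i]], members[[j]]])
        if (dij < best) { best <- dij; bi <- i; bj <- j }
      }
    }
    coph[members[[bi]], members[[bj]]] <- best
    coph[members[[bj]], members[[bi]]] <- best
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
  }
  coph
}

# Small null config (exchangeable samples within each gene).
null_config <- function(n_genes = 10000) {
  synthetic_config(
    species = "human", platform_shift = 0, platform_scale = 1, dropout = 0,
    n_genes = n_genes, n_common = 0, n_pairwise = 0, n_selective = 0,
    multi_frac = 0
  )
}

# Conserved-regional-program config for cross-platform profile clustering.
conserved_config <- function() {
  synthetic_config(n_genes = 2000, n_common = 30, n_pairwise = 5, n_selective = 10)
}

fit_all_species <- function(ds, seed, expressed_threshold = 1) {
  fits <- lapply(seq_along(ds$expression), function(i) {
    suppressMessages(fit_region_specificity(
      ds$expression[[i]], ds$metadata[[i]],
      expressed_threshold = expressed_threshold, seed = seed + i
    ))
  })
  names(fits) <- names(ds$expression)
  fits
}

region_of_leaf <- function(h) {
  labs <- sub(".*_", "", h$labels)
  names(labs) <- h$labels
  labs
}
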