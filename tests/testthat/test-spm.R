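test_that("region design merges ventricles and rejects empty regions", {
  md <- tibble::tibble(
    sample_id = c("a", "b", "c", "d", "e", "f"),
    region = c("LA", "LV", "RV", "SA", "RA", "LA")
  )
  d <- region_design(md)
  expect_setequal(d$region[d$sample_id %in% c("b", "c")], "V")
  expect_false("e" %in% d$sample_id)  # RA outside the region set is dropped
  expect_error(region_design(md[md$region != "SA", ]), "zero samples")
})

test_that("region means average samples within merged regions", {
  m <- matrix(c(2, 4, 6, 8, 1, 9), nrow = 1,
              dimnames = list("g1", c("LV_1", "LV_2", "RV_1", "RV_2", "LA_1", "SA_1")))
  md <- tibble::tibble(sample_id = colnames(m),
                       region = c("LV", "LV", "RV", "RV", "LA", "SA"))
  d <- region_design(md)
  rm_tbl <- region_means(tbl_from_matrix(m), d)
  expect_equal(rm_tbl$V, 5)    # mean of LV (2,4) and RV (6,8) samples
  expect_equal(rm_tbl$LA, 1)   # single-sample region passes through
  expect_equal(rm_tbl$SA, 9)

  extra <- tbl_from_matrix(cbind(m, stray = 3))
  expect_error(region_means(extra, d), "without a region")
})

test_that("SPM is the cosine with a region axis", {
  rm_tbl <- tbl_from_matrix(matrix(
    c(3, 4, 0,
      1, 1, 1,
      0, 0, 5), nrow = 3, byrow = TRUE,
    dimnames = list(c("a", "b", "c"), c("LA", "V", "SA"))
  ))
  spm <- compute_spm(rm_tbl)
  expect_equal(unlist(spm[1, -1], use.names = FALSE), c(0.6, 0.8, 0))
  expect_equal(unlist(spm[2, -1], use.names = FALSE), rep(1 / sqrt(3), 3),
               tolerance = 1e-12)
  expect_equal(unlist(spm[3, -1], use.names = FALSE), c(0, 0, 1))
})

test_that("SPM squared values sum to one and the statistic is scale-invariant", {
  rm_tbl <- withr::with_seed(8, tbl_from_matrix(matrix(
    abs(rnorm(300, 5, 2)), nrow = 100,
    dimnames = list(sprintf("g%03d", 1:100), c("LA", "V", "SA"))
  )))
  spm <- compute_spm(rm_tbl)
  sq <- rowSums(as.matrix(spm[, -1])^2)
  expect_true(all(abs(sq - 1) <= 1e-9))
  expect_true(all(as.matrix(spm[, -1]) >= 0 & as.matrix(spm[, -1]) <= 1))

  scaled <- rm_tbl
  scaled[, -1] <- scaled[, -1] * 7.3
  expect_equal(as.matrix(compute_spm(scaled)[, -1]), as.matrix(spm[, -1]),
               tolerance = 1e-12)

  withzero <- rm_tbl
  withzero[1, -1] <- list(0, 0, 0)
  out <- suppressMessages(compute_spm(withzero))
  expect_equal(attr(out, "excluded_genes"), "g001")
  expect_equal(nrow(out), 99)

  neg <- rm_tbl; neg[2, 2] <- -1
  expect_error(compute_spm(neg), "negative")
})

test_that("SPM increases in a region whose mean grows, and decreases elsewhere", {
  base <- c(LA = 2, V = 3, SA = 4)
  for (bump in c(0.5, 1, 5)) {
    m0 <- tbl_from_matrix(matrix(base, nrow = 1, dimnames = list("g", names(base))))
    m1 <- m0; m1$LA <- m1$LA + bump
    s0 <- compute_spm(m0); s1 <- compute_spm(m1)
    expect_gte(s1$LA, s0$LA)
    expect_lte(s1$V, s0$V)
    expect_lte(s1$SA, s0$SA)
  }
})

test_that("per-gene ANOVA matches the model-fit oracle and handles edge cases", {
  d <- make_design(c("LA", "V", "SA"), c(2, 2, 2))
  m <- matrix(c(1.0, 1.1, 1.05, 0.95, 5.0, 5.1), nrow = 1,
              dimnames = list("g1", d$sample_id))
  res <- anova_per_gene(tbl_from_matrix(m), d)
  expect_lt(res$p_value, 1e-3)
  orc <- oracle_anova(m[1, ], d$region)
  expect_equal(res$f_statistic, orc$f, tolerance = 1e-10)
  expect_equal(res$p_value, orc$p, tolerance = 1e-10)

  # equal group means with within-group variance: F = 0, p = 1
  flat <- matrix(c(1, 3, 1, 3, 1, 3), nrow = 1, dimnames = list("g1", d$sample_id))
  res_flat <- anova_per_gene(tbl_from_matrix(flat), d)
  expect_equal(res_flat$f_statistic, 0)
  expect_equal(res_flat$p_value, 1)

  # identical values everywhere: degenerate, p = 1
  const <- matrix(2, nrow = 1, ncol = 6, dimnames = list("g1", d$sample_id))
  res_const <- anova_per_gene(tbl_from_matrix(const), d)
  expect_true(res_const$degenerate)
  expect_equal(res_const$p_value, 1)

  # perfect separation: p = 0
  sep <- matrix(c(1, 1, 2, 2, 3, 3), nrow = 1, dimnames = list("g1", d$sample_id))
  res_sep <- anova_per_gene(tbl_from_matrix(sep), d)
  expect_equal(res_sep$p_value, 0)

  tiny <- matrix(c(1, 2, 3), nrow = 1,
                 dimnames = list("g1", c("LA_1", "V_1", "SA_1")))
  expect_error(anova_per_gene(tbl_from_matrix(tiny),
                              make_design(c("LA", "V", "SA"), c(1, 1, 1))),
               "more samples than regions")
})

test_that("vectorized ANOVA agrees with the oracle across random designs", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      k <- sample(2:4, 1)
      reps <- sample(2:4, k, replace = TRUE)
      d <- make_design(paste0("R", seq_len(k)), reps)
      m <- matrix(rnorm(3 * sum(reps), 5, 2), nrow = 3,
                  dimnames = list(c("g1", "g2", "g3"), d$sample_id))
      res <- anova_per_gene(tbl_from_matrix(m), d)
      for (g in 1:3) {
        orc <- oracle_anova(m[g, ], d$region)
        expect_equal(res$f_statistic[g], orc$f, tolerance = 1e-10)
        expect_equal(res$p_value[g], orc$p, tolerance = 1e-10)
      }
    }
  })
})

test_that("BH adjustment equals the explicit step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.05, 1.0)), c(0.10, 1.0))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")
  withr::with_seed(7, {
    for (i in 1:200) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), brute_bh(p), tolerance = 0)
    }
  })
})

test_that("permutation null threshold is seeded and handles invariant input", {
  d <- make_design(c("LA", "V", "SA"), c(4, 4, 4))
  # permutation-invariant input: every null SPM is 1/sqrt(3)
  const <- tbl_from_matrix(matrix(rep(c(2, 5, 9), each = 12), nrow = 3, byrow = TRUE,
                                  dimnames = list(c("a", "b", "c"), d$sample_id)))
  nd <- permutation_null_threshold(const, d, seed = 1)
  expect_equal(nd$null_spms, rep(1 / sqrt(3), 9), tolerance = 1e-12)
  expect_equal(nd$threshold, 1 / sqrt(3), tolerance = 1e-12)

  x <- rand_expr(500, d$sample_id, seed = 31)
  nd1 <- permutation_null_threshold(x, d, seed = 99)
  nd2 <- permutation_null_threshold(x, d, seed = 99)
  expect_identical(nd1$threshold, nd2$threshold)
  expect_identical(nd1$null_spms, nd2$null_spms)
  expect_equal(length(nd1$null_spms), 500 * 3)
  expect_true(all(nd1$null_spms >= 0 & nd1$null_spms <= 1))
  nd3 <- permutation_null_threshold(x, d, seed = 100)
  expect_false(identical(nd1$null_spms, nd3$null_spms))
  expect_error(permutation_null_threshold(x, d), "seed")
})

test_that("specific-gene calls require both the SPM and adjusted-p gates", {
  spm <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        LA = c(0.9, 0.9, 0.7), V = c(0.3, 0.3, 0.5),
                        SA = c(0.3, 0.3, 0.5))
  tests <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                          adj_p = c(0.01, 0.20, 0.01))
  calls <- call_specific_genes(spm, tests, 0.8, alpha = 0.05)
  la <- calls[calls$region == "LA", ]
  expect_equal(la$is_specific[la$gene_id == "g1"], TRUE)   # passes both
  expect_equal(la$is_specific[la$gene_id == "g2"], FALSE)  # fails adj p
  expect_equal(la$is_specific[la$gene_id == "g3"], FALSE)  # fails SPM
  expect_false(any(calls$multi_region))
  expect_error(call_specific_genes(spm, tests[-1, ], 0.8), "same genes")

  # a low threshold can admit two regions; the gene is flagged
  spm2 <- tibble::tibble(gene_id = "g1", LA = 0.7, V = 0.7, SA = 0.14)
  calls2 <- call_specific_genes(spm2, tests[1, ], 0.6)
  expect_equal(sum(calls2$is_specific), 2)
  expect_true(all(calls2$multi_region))
})

test_that("z-scored SPM columns have mean zero and unit sd", {
  spm <- tbl_from_matrix(matrix(c(0.2, 0.4, 0.6, 0.5, 0.5, 0.5), ncol = 2,
                                dimnames = list(c("a", "b", "c"), c("LA", "V"))))
  expect_warning(z <- zscore_spm(spm), "zero-variance")
  expect_equal(z$LA, c(-1, 0, 1))
  expect_equal(z$V, c(0, 0, 0))

  big <- withr::with_seed(5, tbl_from_matrix(matrix(runif(300), ncol = 3,
    dimnames = list(sprintf("g%d", 1:100), c("LA", "V", "SA")))))
  zb <- zscore_spm(big)
  expect_equal(colMeans(as.matrix(zb[, -1])), rep(0, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(apply(as.matrix(zb[, -1]), 2, sd), rep(1, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the fit object summarizes through tidy and glance", {
  ds <- generate_dataset(synthetic_config(n_genes = 300, n_common = 2,
                                          n_pairwise = 1, n_selective = 2),
                         seed = 12)
  fit <- suppressMessages(fit_region_specificity(
    ds$expression$human, ds$metadata$human, expressed_threshold = 1, seed = 99
  ))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("gene_id", "region", "spm", "adj_p", "tau", "is_specific")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_specific, sum(td$is_specific))
  expect_equal(nrow(td), gl$n_genes * 3)
  tops <- specific_gene_table(fit)
  expect_true(all(tops$gene_id %in% td$gene_id[td$is_specific]))
})
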