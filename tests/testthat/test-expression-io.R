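test_that("log2 transform maps v to log2(v + 1) and round-trips", {
  x <- tbl_from_matrix(matrix(c(0, 1, 7, 3), nrow = 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))))
  out <- log2_transform(x)
  expect_equal(out$s1, c(0, 1))
  expect_equal(out$s2, c(3, 2))

  y <- rand_expr(50, c("s1", "s2", "s3"), seed = 11, mean = 4, sd = 1)
  lin <- tbl_from_matrix(2^as.matrix(tibble::column_to_rownames(y, "gene_id")) - 1)
  expect_equal(as.matrix(log2_transform(lin)[, -1]), as.matrix(y[, -1]),
               tolerance = 1e-12)

  neg <- x; neg$s1[1] <- -0.5
  expect_error(log2_transform(neg), "negative.*'a'.*'s1'")
})

test_that("pseudocount shifts every value and rejects c <= 0", {
  x <- tbl_from_matrix(matrix(c(0, 2.5), nrow = 1,
                              dimnames = list("g", c("s1", "s2"))))
  out <- add_pseudocount(x, 1)
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(1, 3.5))
  expect_error(add_pseudocount(x, 0), "positive")
  expect_error(add_pseudocount(x, -1), "positive")
})

test_that("median alignment equalizes per-sample medians at the grand median", {
  m <- matrix(c(1, 3, 5, 3, 5, 7), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  out <- median_align(tbl_from_matrix(m))
  expect_equal(median(out$s1), 4)
  expect_equal(median(out$s2), 4)

  one <- tbl_from_matrix(m[, 1, drop = FALSE])
  expect_equal(median_align(one), one)

  # constant-shifted copies of one sample collapse to identical columns
  shifted <- tbl_from_matrix(cbind(s1 = m[, 1], s2 = m[, 1] + 2, s3 = m[, 1] - 5))
  al <- median_align(shifted)
  expect_equal(al$s2, al$s1, tolerance = 1e-12)
  expect_equal(al$s3, al$s1, tolerance = 1e-12)

  big <- rand_expr(200, sprintf("s%d", 1:6), seed = 3)
  ab <- median_align(big)
  meds <- apply(as.matrix(ab[, -1]), 2, median)
  expect_lt(max(meds) - min(meds), 1e-12)
  # rank order preserved within each sample
  expect_equal(order(ab$s1), order(big$s1))
})

test_that("percentile normalization equalizes the q-th percentiles", {
  big <- rand_expr(200, sprintf("s%d", 1:5), seed = 4)
  out <- percentile_normalize(big, q = 90)
  p90 <- apply(as.matrix(out[, -1]), 2, quantile, probs = 0.9, type = 7)
  expect_lt(max(p90) - min(p90), 1e-12)
  expect_equal(order(out$s2), order(big$s2))

  same <- tbl_from_matrix(matrix(rep(1:10, 2), ncol = 2,
                                 dimnames = list(sprintf("g%d", 1:10), c("a", "b"))))
  expect_equal(percentile_normalize(same), same)
  expect_error(percentile_normalize(big, q = 0), "percentile")
  expect_error(percentile_normalize(big, q = 100), "percentile")
})

test_that("rows with missing values are dropped and counted", {
  x <- rand_expr(5, c("s1", "s2"), seed = 9)
  x$s1[3] <- NA
  out <- suppressMessages(drop_incomplete_rows(x))
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "n_removed"), 1)
  expect_equal(drop_incomplete_rows(out), out, ignore_attr = TRUE)

  all_na <- x; all_na$s2 <- NA_real_
  expect_warning(res <- suppressMessages(drop_incomplete_rows(all_na)), "empty")
  expect_equal(nrow(res), 0)
})

test_that("probe collapse takes the element-wise maximum per gene", {
  m <- withr::with_seed(21, matrix(rnorm(8 * 3, 5), nrow = 8,
                                   dimnames = list(sprintf("p%d", 1:8),
                                                   c("s1", "s2", "s3"))))
  pm <- tibble::tibble(probe_id = sprintf("p%d", 1:7),
                       gene_id = c("A", "A", "A", "B", "B", "C", "C"))
  out <- suppressMessages(collapse_probes(tbl_from_matrix(m), pm))
  expect_equal(attr(out, "n_unmapped"), 1)  # p8 dropped
  expect_setequal(out$gene_id, c("A", "B", "C"))
  # brute-force scan per gene and sample
  om <- as.matrix(tibble::column_to_rownames(out, "gene_id"))
  for (g in c("A", "B", "C")) {
    probes <- pm$probe_id[pm$gene_id == g]
    for (s in colnames(m)) {
      expect_equal(om[g, s], max(m[probes, s]))
    }
  }
  # one probe per gene is a relabeled identity
  pm1 <- tibble::tibble(probe_id = rownames(m), gene_id = paste0("G", rownames(m)))
  out1 <- collapse_probes(tbl_from_matrix(m), pm1)
  expect_equal(unname(as.matrix(out1[order(out1$gene_id), -1])),
               unname(m[order(paste0("G", rownames(m))), ]))
  expect_error(collapse_probes(tbl_from_matrix(m), pm[0, ]), "empty")
})

test_that("expression filter is strict and idempotent", {
  m <- matrix(c(0.5, 6.2, 1.0, 0.2, 5.9, 0.9), nrow = 3,
              dimnames = list(c("low", "hi", "edge"), c("s1", "s2")))
  x <- tbl_from_matrix(m)
  expect_equal(filter_expressed(x, 1)$gene_id, "hi")     # strict: 1.0 not > 1
  expect_equal(filter_expressed(x, 6)$gene_id, "hi")     # 6.2 > 6 kept
  expect_equal(filter_expressed(x, -Inf), x)
  f <- filter_expressed(x, 0.8)
  expect_equal(filter_expressed(f, 0.8), f)
})

test_that("TPM columns sum to 1e6 and follow the per-kilobase rates", {
  counts <- tbl_from_matrix(matrix(c(10, 90), nrow = 2,
                                   dimnames = list(c("g1", "g2"), "s1")))
  gl <- tibble::tibble(gene_id = c("g1", "g2"), length = c(1000, 9000))
  tpm <- compute_tpm(counts, gl)
  expect_equal(tpm$s1, c(5e5, 5e5))

  single <- tbl_from_matrix(matrix(7, nrow = 1, dimnames = list("g1", "s1")))
  expect_equal(compute_tpm(single, gl[1, ])$s1, 1e6)

  zc <- tbl_from_matrix(matrix(c(0, 5), nrow = 2,
                               dimnames = list(c("g1", "g2"), "s1")))
  expect_equal(compute_tpm(zc, gl)$s1, c(0, 1e6))

  ct <- generate_count_table(100, 4, seed = 5)
  tpm2 <- compute_tpm(ct$counts, ct$gene_lengths)
  expect_equal(colSums(as.matrix(tpm2[, -1])), rep(1e6, 4),
               tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(compute_tpm(counts, tibble::tibble(gene_id = c("g1", "g2"),
                                                  length = c(0, 100))),
               "positive")
  zero_sample <- tbl_from_matrix(matrix(0, nrow = 2, ncol = 1,
                                        dimnames = list(c("g1", "g2"), "s1")))
  expect_warning(z <- compute_tpm(zero_sample, gl), "all-zero")
  expect_equal(z$s1, c(0, 0))
})

test_that("TSV round-trips preserve values and missingness", {
  x <- rand_expr(10, c("s1", "s2"), seed = 2)
  x$s1[4] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(x, path)
  y <- read_expression_tsv(path)
  expect_equal(y, x)

  md_path <- withr::local_tempfile(fileext = ".tsv")
  md <- tibble::tibble(sample_id = c("a", "b"), species = "human",
                       region = c("LA", "SA"), individual_id = c("i1", "i2"),
                       platform_id = "rnaseq")
  readr::write_tsv(md, md_path)
  expect_equal(read_sample_metadata(md_path), md)
  readr::write_tsv(md[, -2], md_path)
  expect_error(read_sample_metadata(md_path), "lacks columns")
})
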