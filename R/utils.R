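# Internal helpers shared across modules.

# Convert a tibble whose first column is a gene/probe/sample id into a numeric
# matrix with ids as rownames. All value columns must be numeric.
expr_matrix <- function(x) {
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("expected a data frame with an id column followed by value columns")
  }
  ids <- as.character(x[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate ids in first column: ", paste(head(dup, 5), collapse = ", ")))
  }
  vals <- x[, -1, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric value columns: ", paste(head(bad, 5), collapse = ", ")))
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Inverse of expr_matrix().
expr_tibble <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  bind_cols(tibble(!!id_col := rownames(m)), out)
}

# Percentile with the linear-interpolation convention (quantile type 7),
# used everywhere a percentile is taken so normalization and the permutation
# threshold share one definition.
pctl <- function(x, q) {
  quantile(x, probs = q / 100, type = 7, names = FALSE)
}

id_col_name <- function(x) names(x)[1]

stop_if_empty <- function(x, what) {
  if (nrow(x) == 0 || ncol(x) < 2) abort(paste0("empty ", what))
  invisible(x)
}
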