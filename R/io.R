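#' Read a gene-by-sample expression table
#'
#' Reads a tab-separated expression table: header row of sample ids, first
#' column gene (or probe) ids, remaining columns numeric intensities, `NA`
#' for missing values.
#'
#' @param path Path to a TSV file.
#' @param id_col Name to give the id column (default `"gene_id"`).
#' @return A tibble with the id column first and one numeric column per sample.
#' @export
read_expression_tsv <- function(path, id_col = "gene_id") {
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 2) abort("expression table needs an id column plus >= 1 sample")
  names(x)[1] <- id_col
  x[[1]] <- as.character(x[[1]])
  if (anyDuplicated(x[[1]])) abort("duplicate ids in expression table")
  x
}

#' Write an expression table as TSV
#'
#' @param x Expression tibble (id column first).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(x)
}

#' Read per-sample metadata
#'
#' The metadata TSV must contain the columns `sample_id`, `species`, `region`,
#' `individual_id` and `platform_id`; `sample_id` must be unique and no field
#' may be missing.
#'
#' @param path Path to a TSV file.
#' @return A tibble with the five required columns (extra columns are kept).
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "species", "region", "individual_id", "platform_id")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(md$sample_id)) abort("duplicate sample_id in metadata")
  if (anyNA(md[required])) abort("missing values in required metadata columns")
  md
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (`probe_id`, `gene_id`). Many probes per gene are allowed;
#' a probe mapping to more than one gene is an error.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `probe_id` and `gene_id`.
#' @export
read_probe_map <- function(path) {
  pm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(pm) < 2) abort("probe map needs two columns (probe_id, gene_id)")
  pm <- distinct(tibble(probe_id = as.character(pm[[1]]), gene_id = as.character(pm[[2]])))
  multi <- pm |> count(.data$probe_id) |> filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(paste0("probes mapping to multiple genes: ",
                 paste(head(multi$probe_id, 5), collapse = ", ")))
  }
  pm
}

#' Read a pairwise ortholog table
#'
#' Biomart-style export: first column genes of the x-species, second column
#' orthologous genes of the y-species; many-to-many rows permitted, duplicates
#' dropped, extra columns ignored.
#'
#' @param path Path to a TSV file with a header row.
#' @param x_species,y_species Species labels for the two columns.
#' @return A tibble with columns `x_gene`, `y_gene` and attributes
#'   `x_species`/`y_species`.
#' @export
read_ortholog_table <- function(path, x_species, y_species) {
  ot <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(ot) < 2) abort("ortholog table needs two columns")
  ortholog_table(
    tibble(x_gene = as.character(ot[[1]]), y_gene = as.character(ot[[2]])),
    x_species, y_species
  )
}

#' Construct an ortholog table from a data frame
#'
#' @param pairs Data frame whose first two columns are x-species and y-species
#'   gene ids.
#' @param x_species,y_species Species labels.
#' @return A deduplicated tibble with columns `x_gene`, `y_gene` and species
#'   attributes.
#' @export
ortholog_table <- function(pairs, x_species, y_species) {
  ot <- tibble(x_gene = as.character(pairs[[1]]), y_gene = as.character(pairs[[2]]))
  if (any(!nzchar(ot$x_gene)) || any(!nzchar(ot$y_gene)) || anyNA(ot)) {
    abort("ortholog table has empty or missing gene ids")
  }
  ot <- distinct(ot)
  attr(ot, "x_species") <- x_species
  attr(ot, "y_species") <- y_species
  ot
}

#' Read a gene-length table
#'
#' @param path TSV with columns gene id and length (base pairs).
#' @return Tibble with columns `gene_id`, `length`.
#' @export
read_gene_lengths <- function(path) {
  gl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(gl) < 2) abort("gene length table needs two columns")
  out <- tibble(gene_id = as.character(gl[[1]]), length = as.numeric(gl[[2]]))
  if (any(!is.finite(out$length)) || any(out$length <= 0)) {
    abort("gene lengths must be positive")
  }
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `term_id`, description, then
#' member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return A long tibble with columns `term_id`, `term_name`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort("GMT line needs term, description and >= 1 gene")
    tibble(term_id = f[1], term_name = f[2], gene = f[-(1:2)])
  })
  out <- bind_rows(rows)
  if (anyDuplicated(unique(out[, c("term_id", "term_name")])$term_id)) {
    abort("duplicate term ids in GMT")
  }
  distinct(out)
}

#' Read a two-column term-to-gene annotation table
#'
#' @param path TSV with columns term id and gene id (header required).
#' @return A long tibble with columns `term_id`, `term_name` (copied from the
#'   id), `gene`.
#' @export
read_term_map <- function(path) {
  tm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tm) < 2) abort("term map needs two columns (term_id, gene)")
  distinct(tibble(
    term_id = as.character(tm[[1]]),
    term_name = as.character(tm[[1]]),
    gene = as.character(tm[[2]])
  ))
}
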