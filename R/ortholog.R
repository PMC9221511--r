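# Cross-species comparison via many-to-many ortholog tables.

# Return an x->y pair tibble between `from` and `to`, flipping a stored table
# if it is oriented the other way.
pair_table <- function(tables, from, to) {
  for (ot in tables) {
    xs <- attr(ot, "x_species")
    ys <- attr(ot, "y_species")
    if (identical(xs, from) && identical(ys, to)) return(ot)
    if (identical(xs, to) && identical(ys, from)) {
      return(ortholog_table(tibble(x_gene = ot$y_gene, y_gene = ot$x_gene), from, to))
    }
  }
  abort(sprintf("no ortholog table for %s vs %s", from, to))
}

#' Pair expression values across species through orthologs
#'
#' Indexes on the x-species: every x gene with at least one ortholog that has
#' a y value is paired with the arithmetic mean of its mapped y values
#' (the averaging rule for one-to-many families). x genes without any mapped
#' y value are dropped and counted.
#'
#' @param x_values Tibble: x-species gene ids in column 1, values in column 2.
#' @param y_values Tibble: y-species gene ids in column 1, values in column 2.
#' @param orthologs Ortholog table oriented x -> y (see [ortholog_table()]).
#' @return Tibble `x_gene`, `x_value`, `y_value`, with attributes `n_mapped`
#'   and `n_dropped`.
#' @export
map_orthologs <- function(x_values, y_values, orthologs) {
  if (nrow(orthologs) == 0) abort("empty ortholog table")
  xv <- tibble(x_gene = as.character(x_values[[1]]), x_value = as.numeric(x_values[[2]]))
  yv <- tibble(y_gene = as.character(y_values[[1]]), y_value = as.numeric(y_values[[2]]))
  mapped <- xv |>
    inner_join(orthologs, by = "x_gene", relationship = "many-to-many") |>
    inner_join(yv, by = "y_gene") |>
    group_by(.data$x_gene, .data$x_value) |>
    summarise(y_value = mean(.data$y_value), .groups = "drop") |>
    select("x_gene", "x_value", "y_value")
  out <- xv |> select("x_gene") |> inner_join(mapped, by = "x_gene")
  attr(out, "n_mapped") <- nrow(out)
  attr(out, "n_dropped") <- nrow(xv) - nrow(out)
  out
}

#' Interspecies Spearman correlation for one region
#'
#' Spearman rank correlation (mid-ranks for ties) of region-mean expression
#' between two species over ortholog-mapped gene pairs, y-side values
#' averaged for one-to-many families.
#'
#' @param rm_x,rm_y Region-means tibbles ([region_means()]) for the x- and
#'   y-species.
#' @param orthologs Ortholog table oriented x -> y.
#' @param region Region column present in both tibbles.
#' @return A single correlation in \[-1, 1\]; errors with < 3 mapped pairs or
#'   zero rank variance.
#' @export
interspecies_spearman <- function(rm_x, rm_y, orthologs, region) {
  for (nm in list(rm_x, rm_y)) {
    if (!region %in% names(nm)) abort(sprintf("region '%s' absent from region means", region))
  }
  pairs <- map_orthologs(
    rm_x[, c(id_col_name(rm_x), region)],
    rm_y[, c(id_col_name(rm_y), region)],
    orthologs
  )
  if (nrow(pairs) < 3) abort("fewer than 3 mapped ortholog pairs")
  if (length(unique(pairs$x_value)) < 2 || length(unique(pairs$y_value)) < 2) {
    abort("zero rank variance on one side")
  }
  cor(pairs$x_value, pairs$y_value, method = "spearman")
}

#' Classify specific genes as species-common, pairwise or species-selective
#'
#' For every (gene, region) called specific in the index species, looks up
#' its orthologs in each other species and asks whether any ortholog is
#' specific for the same region there. Agreement in all species gives
#' `common_all`; agreement with exactly one other species gives `pairwise`;
#' no agreement gives `selective`. Genes without orthologs in a species
#' cannot agree with it, hence cannot be `common_all`.
#'
#' @param calls_by_species Named list (one element per species) of calls
#'   tibbles from [call_specific_genes()] or `spm_fit$calls`.
#' @param tables List of ortholog tables covering every needed species pair
#'   (orientation is handled automatically).
#' @param reference Index species (default `"human"`); categories are
#'   reported on its gene ids.
#' @param per_species If `TRUE`, classify every species' calls (each species
#'   as its own index) and return the combined table with an `index_species`
#'   column.
#' @return Tibble `gene_id`, `region`, `category`
#'   (`common_all`/`pairwise`/`selective`), `species_set` (comma-separated,
#'   sorted agreeing species including the index), `n_agree`.
#' @export
categorize_specific_sets <- function(calls_by_species, tables,
                                     reference = "human",
                                     per_species = FALSE) {
  species <- names(calls_by_species)
  if (is.null(species) || any(!nzchar(species))) {
    abort("calls_by_species must be a named list")
  }
  if (!reference %in% species) abort(sprintf("species '%s' missing from calls", reference))
  spec_pairs <- function(s) {
    calls_by_species[[s]] |>
      filter(.data$is_specific) |>
      distinct(.data$gene_id, .data$region)
  }
  classify_one <- function(idx) {
    sp <- spec_pairs(idx)
    others <- setdiff(species, idx)
    agree <- matrix(FALSE, nrow = nrow(sp), ncol = length(others),
                    dimnames = list(NULL, others))
    for (s in others) {
      ot <- pair_table(tables, idx, s)
      other_spec <- spec_pairs(s)
      hits <- sp |>
        inner_join(ot, by = c(gene_id = "x_gene"), relationship = "many-to-many") |>
        inner_join(other_spec, by = c(y_gene = "gene_id", region = "region")) |>
        distinct(.data$gene_id, .data$region)
      agree[, s] <- paste(sp$gene_id, sp$region) %in% paste(hits$gene_id, hits$region)
    }
    n_agree <- rowSums(agree)
    category <- case_when(
      n_agree == length(others) ~ "common_all",
      n_agree == 0 ~ "selective",
      TRUE ~ "pairwise"
    )
    species_set <- vapply(seq_len(nrow(sp)), function(i) {
      paste(sort(c(idx, others[agree[i, ]])), collapse = ",")
    }, character(1))
    sp |> mutate(category = category, species_set = species_set,
                 n_agree = n_agree, index_species = idx)
  }
  if (per_species) {
    bind_rows(lapply(species, classify_one))
  } else {
    classify_one(reference) |> select(-"index_species")
  }
}

#' Rank transcription factors of a gene set by SPM
#'
#' Intersects a gene set with a transcription-factor set (e.g. genes
#' annotated to GO:0003700), sorts by the region's SPM value descending and
#' keeps the top `k`; ties are broken lexicographically by gene id.
#'
#' @param genes Character vector of gene ids.
#' @param spm SPM tibble from [compute_spm()].
#' @param region Region whose SPM values rank the genes.
#' @param tf_set Character vector of transcription-factor gene ids.
#' @param k Maximum number of genes returned (default 5).
#' @return Tibble `gene_id`, `spm`, `rank`.
#' @export
annotate_and_rank <- function(genes, spm, region, tf_set, k = 5) {
  if (!region %in% names(spm)) abort(sprintf("region '%s' absent from SPM table", region))
  id <- id_col_name(spm)
  out <- spm |>
    filter(.data[[id]] %in% genes, .data[[id]] %in% tf_set) |>
    select(gene_id = all_of(id), spm = all_of(region)) |>
    arrange(desc(.data$spm), .data$gene_id) |>
    head(k)
  out$rank <- seq_len(nrow(out))
  out
}
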