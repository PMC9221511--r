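# Hierarchical clustering of samples and of SPM profiles.

# 1 - Spearman correlation distance between the columns of a matrix.
spearman_distance <- function(m) {
  const <- vapply(seq_len(ncol(m)), function(j) length(unique(m[, j])) == 1, logical(1))
  if (any(const)) {
    abort(paste0("constant columns have undefined correlation: ",
                 paste(colnames(m)[const], collapse = ", ")))
  }
  as.dist(1 - cor(m, method = "spearman"))
}

#' Hierarchically cluster samples
#'
#' Average-linkage (UPGMA) agglomeration of the samples of an expression
#' table under the 1 - Spearman correlation distance between sample columns.
#' Distances lie in \[0, 2\]; identical rankings merge at height 0.
#' Spearman makes the tree invariant to monotone per-sample transforms.
#'
#' @param x Expression tibble with >= 2 samples.
#' @return An [stats::hclust] tree with sample labels.
#' @export
cluster_samples <- function(x) {
  m <- expr_matrix(x)
  if (ncol(m) < 2) abort("need >= 2 samples to cluster")
  hclust(spearman_distance(m), method = "average")
}

#' Assemble cross-species SPM profiles on a shared gene index
#'
#' Restricts to reference-species genes having at least one ortholog with an
#' SPM value in every other species, then maps each other species' SPM values
#' onto that index ([map_orthologs()] averaging). With three species and
#' three regions this yields the nine species-region profile vectors used for
#' cross-platform clustering.
#'
#' @param spm_by_species Named list of SPM tibbles ([compute_spm()]).
#' @param tables List of ortholog tables covering reference vs each species.
#' @param reference Indexing species (default `"human"`).
#' @return Tibble: `gene_id` (reference ids) + one column per species-region
#'   pair named `<species>_<region>`.
#' @export
build_spm_profile_set <- function(spm_by_species, tables, reference = "human") {
  species <- names(spm_by_species)
  if (!reference %in% species) abort("reference species missing from SPM list")
  ref_spm <- spm_by_species[[reference]]
  id <- id_col_name(ref_spm)
  regions <- names(ref_spm)[-1]
  others <- setdiff(species, reference)

  mapped <- list()
  shared <- ref_spm[[1]]
  for (s in others) {
    ot <- pair_table(tables, reference, s)
    spm_s <- spm_by_species[[s]]
    for (r in regions) {
      mp <- map_orthologs(ref_spm[, c(id, r)], spm_s[, c(id_col_name(spm_s), r)], ot)
      mapped[[paste(s, r, sep = "_")]] <- mp
      shared <- intersect(shared, mp$x_gene)
    }
  }
  if (length(shared) == 0) abort("no reference genes with orthologs in every species")
  out <- tibble(gene_id = shared)
  for (r in regions) {
    out[[paste(reference, r, sep = "_")]] <-
      ref_spm[[r]][match(shared, ref_spm[[1]])]
  }
  for (s in others) {
    for (r in regions) {
      mp <- mapped[[paste(s, r, sep = "_")]]
      out[[paste(s, r, sep = "_")]] <- mp$y_value[match(shared, mp$x_gene)]
    }
  }
  out
}

#' Hierarchically cluster SPM profiles
#'
#' Average-linkage clustering of the species-region SPM profile vectors under
#' the 1 - Spearman distance, reproducing the cross-platform grouping of
#' regions regardless of platform when regional signal dominates.
#'
#' @param profiles Profile tibble from [build_spm_profile_set()] (>= 2
#'   profiles of length >= 3).
#' @return An [stats::hclust] tree with species-region labels.
#' @export
cluster_spm_profiles <- function(profiles) {
  m <- expr_matrix(profiles)
  if (ncol(m) < 2) abort("need >= 2 profiles")
  if (nrow(m) < 3) abort("profiles must have length >= 3")
  hclust(spearman_distance(m), method = "average")
}

#' Serialize a dendrogram to Newick
#'
#' @param h An [stats::hclust] tree.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly if `path` is given). Merge heights
#'   become branch lengths.
#' @export
dendrogram_newick <- function(h, path = NULL) {
  phy <- ape::as.phylo(h)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    readr::write_lines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Label purity of a k-cluster cut
#'
#' Cuts a tree into `k` clusters and scores how homogeneously an external
#' label (e.g. the cardiac region of each leaf) fills each cluster: the
#' purity is the weighted mean, over clusters, of the modal label fraction.
#' Purity 1 means every cluster is label-pure.
#'
#' @param h An [stats::hclust] tree.
#' @param k Number of clusters to cut into.
#' @param labels Character vector of leaf labels, named by `h$labels` or in
#'   the same order.
#' @return A number in (0, 1\].
#' @export
cluster_label_purity <- function(h, k, labels) {
  ct <- cutree(h, k = k)
  if (!is.null(names(labels))) labels <- labels[names(ct)]
  if (length(labels) != length(ct) || anyNA(labels)) {
    abort("labels must cover every leaf")
  }
  sum(vapply(split(labels, ct), function(l) max(table(l)), numeric(1))) / length(ct)
}
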