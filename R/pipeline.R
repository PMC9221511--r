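#' Default pipeline configuration
#'
#' A pipeline run is described by a plain list. In simulation mode
#' (`synthetic` set) the stages are: simulate, preprocess (expression filter +
#' median alignment), specificity (SPM + ANOVA + permutation threshold +
#' calls per species), categorize (cross-species common/pairwise/selective),
#' cluster (per-species sample trees and the cross-species SPM-profile tree)
#' and enrich (over-representation of each region's specific set against the
#' planted-region annotation, background = analysis universe). Input mode
#' replaces the simulate stage by reading per-species expression/metadata
#' TSVs.
#'
#' @param synthetic A [synthetic_config()] (or `NULL` for input mode).
#' @param inputs Input mode: named list per species with elements
#'   `expression`, `metadata` (paths), optional `scale` (`"log2"` or
#'   `"linear"`), optional `normalize` (`"median"`, `"percentile90"`,
#'   `"none"`) and optional `probe_map` path.
#' @param expressed_threshold Per-species named vector (or single value) of
#'   expression filter thresholds, strict `>` in at least one sample.
#' @param regions,merge Region set and merge rules (see [region_design()]).
#' @param alpha BH-adjusted p cutoff.
#' @param percentile Permutation-null percentile defining tau.
#' @param seed Default seed (overridable in [run_pipeline()]).
#' @param annotation Optional path to a GMT or two-column term map used by
#'   the enrich stage in input mode.
#' @return Config list for [run_pipeline()].
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            inputs = NULL,
                            expressed_threshold = 1,
                            regions = c("LA", "V", "SA"),
                            merge = c(LV = "V", RV = "V"),
                            alpha = 0.05,
                            percentile = 95,
                            seed = 1L,
                            annotation = NULL) {
  list(
    synthetic = synthetic, inputs = inputs,
    expressed_threshold = expressed_threshold,
    regions = regions, merge = merge, alpha = alpha,
    percentile = percentile, seed = seed, annotation = annotation
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the [pipeline_config()] defaults; a `synthetic`
#' block is passed to [synthetic_config()].
#'
#' @param path YAML file.
#' @return Config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) {
    do.call(synthetic_config, lapply(y$synthetic, function(v) {
      if (is.list(v)) unlist(v) else v
    }))
  } else NULL
  cfg <- pipeline_config(synthetic = syn)
  for (nm in setdiff(names(y), "synthetic")) cfg[[nm]] <- y[[nm]]
  if (!is.null(cfg$expressed_threshold)) {
    cfg$expressed_threshold <- unlist(cfg$expressed_threshold)
  }
  cfg
}

run_stage <- function(name, manifest_env, expr) {
  inform(sprintf("[%s] running", name))
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  manifest_env$stages <- c(manifest_env$stages, name)
  res
}

threshold_for <- function(threshold, sp) {
  if (length(threshold) == 1 && is.null(names(threshold))) return(unname(threshold))
  if (!sp %in% names(threshold)) abort(sprintf("no expression threshold for %s", sp))
  unname(threshold[[sp]])
}

#' Run the full region-specificity pipeline
#'
#' Executes every stage (see [pipeline_config()]) and writes all outputs to
#' `out_dir`: per species the processed expression, SPM table with test
#' results, calls table and null-distribution JSON; the cross-species
#' category table; Newick dendrograms for samples and SPM profiles;
#' interspecies Spearman correlations; enrichment tables; and
#' `manifest.json` (config hash, seed, completed stages, per-stage row
#' counts). A rerun with the same config and seed reproduces every output
#' byte-identically.
#'
#' @param config List from [pipeline_config()] or [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Invisibly, a list with the fitted objects, categories, trees,
#'   scores (simulation mode) and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = config$seed) {
  if (missing(out_dir)) abort("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env()
  env$stages <- character()
  counts <- list()
  simulate_mode <- !is.null(config$synthetic)

  # --- stage 1: simulate or load -------------------------------------------
  ds <- if (simulate_mode) {
    run_stage("simulate", env, generate_dataset(config$synthetic, seed = seed))
  } else {
    run_stage("load", env, {
      if (is.null(config$inputs)) abort("config has neither synthetic nor inputs")
      expression <- list(); metadata <- list()
      for (sp in names(config$inputs)) {
        inp <- config$inputs[[sp]]
        x <- read_expression_tsv(inp$expression)
        x <- drop_incomplete_rows(x)
        if (!is.null(inp$probe_map)) {
          x <- collapse_probes(x, read_probe_map(inp$probe_map))
        }
        if (identical(inp$scale %||% "log2", "linear")) x <- log2_transform(x)
        norm <- inp$normalize %||% "median"
        x <- switch(norm,
          median = median_align(x),
          percentile90 = percentile_normalize(x, 90),
          none = x,
          abort(sprintf("unknown normalization '%s'", norm))
        )
        expression[[sp]] <- floor_at_zero(x)
        metadata[[sp]] <- read_sample_metadata(inp$metadata)
      }
      orthologs <- list()
      if (!is.null(config$ortholog_tables)) {
        for (ot in config$ortholog_tables) {
          orthologs[[paste(ot$x_species, ot$y_species, sep = "_")]] <-
            read_ortholog_table(ot$path, ot$x_species, ot$y_species)
        }
      }
      list(expression = expression, metadata = metadata, orthologs = orthologs,
           truth = NULL)
    })
  }
  if (simulate_mode) {
    # synthetic values are already on the log2 scale; align platform medians,
    # then floor at 0 (alignment can nudge near-zero log2 values negative,
    # and the SPM statistic requires non-negative means)
    ds$expression <- run_stage("preprocess", env, {
      lapply(ds$expression, function(x) floor_at_zero(median_align(x)))
    })
  } else {
    env$stages <- c(env$stages, "preprocess")  # folded into load above
  }
  species <- names(ds$expression)
  counts$genes_in <- map_dbl(ds$expression, nrow)

  # --- stage: specificity ---------------------------------------------------
  fits <- run_stage("specificity", env, {
    out <- list()
    for (i in seq_along(species)) {
      sp <- species[i]
      out[[sp]] <- fit_region_specificity(
        ds$expression[[sp]], ds$metadata[[sp]],
        regions = config$regions, merge = config$merge,
        expressed_threshold = threshold_for(config$expressed_threshold, sp),
        alpha = config$alpha, percentile = config$percentile,
        seed = as.integer(seed) + i
      )
    }
    out
  })
  counts$genes_analyzed <- map_dbl(fits, ~ nrow(.x$spm))
  counts$specific_calls <- map_dbl(fits, ~ sum(.x$calls$is_specific))

  # --- stage: categorize ----------------------------------------------------
  reference <- if (simulate_mode) ds$truth$reference_species else species[1]
  categories <- run_stage("categorize", env, {
    if (length(ds$orthologs) == 0) abort("no ortholog tables available")
    categorize_specific_sets(
      lapply(fits, `[[`, "calls"), ds$orthologs, reference = reference
    )
  })
  counts$categories <- nrow(categories)

  # --- stage: cluster -------------------------------------------------------
  trees <- run_stage("cluster", env, {
    sample_trees <- lapply(ds$expression, cluster_samples)
    profiles <- build_spm_profile_set(
      lapply(fits, `[[`, "spm"), ds$orthologs, reference = reference
    )
    list(samples = sample_trees, profiles = profiles,
         profile_tree = cluster_spm_profiles(profiles))
  })

  correlations <- {
    prs <- combn(species, 2, simplify = FALSE)
    rows <- list()
    for (pr in prs) {
      ot <- pair_table(ds$orthologs, pr[1], pr[2])
      for (r in config$regions) {
        rho <- interspecies_spearman(
          region_means(fits[[pr[1]]]$expression, fits[[pr[1]]]$design),
          region_means(fits[[pr[2]]]$expression, fits[[pr[2]]]$design),
          ot, r
        )
        rows[[length(rows) + 1]] <- tibble(
          x_species = pr[1], y_species = pr[2], region = r, rho = rho
        )
      }
    }
    bind_rows(rows)
  }

  # --- stage: enrich --------------------------------------------------------
  enrichment <- run_stage("enrich", env, {
    annotation <- if (!is.null(config$annotation)) {
      if (grepl("\\.gmt$", config$annotation)) read_gmt(config$annotation)
      else read_term_map(config$annotation)
    } else if (simulate_mode) {
      # built-in annotation: each region's planted reference genes as a term
      tr <- ds$truth$per_species[[reference]] |> filter(.data$present)
      bind_rows(lapply(config$regions, function(r) {
        g <- tr$gene_id[tr$region == r]
        if (length(g) == 0) return(NULL)
        tibble(term_id = paste0("PLANTED_", r), term_name = paste0("planted ", r),
               gene = g)
      }))
    } else NULL
    if (is.null(annotation) || nrow(annotation) == 0) {
      NULL
    } else {
      background <- fits[[reference]]$spm[[1]]
      lapply(setNames(config$regions, config$regions), function(r) {
        q <- fits[[reference]]$calls |>
          filter(.data$is_specific, .data$region == r) |>
          pull(.data$gene_id)
        if (length(q) == 0) return(NULL)
        enrich(q, background, annotation, alpha = config$alpha)
      })
    }
  })

  scores <- if (simulate_mode) {
    score_recovery(fits, categories, ds$truth)
  } else NULL

  # --- write outputs --------------------------------------------------------
  for (sp in species) {
    fit <- fits[[sp]]
    write_expression_tsv(fit$expression, file.path(out_dir, paste0(sp, "_expression.tsv")))
    spm_out <- fit$spm |>
      left_join(fit$tests, by = setNames("gene_id", id_col_name(fit$spm)))
    readr::write_tsv(spm_out, file.path(out_dir, paste0(sp, "_spm.tsv")), progress = FALSE)
    readr::write_tsv(fit$calls, file.path(out_dir, paste0(sp, "_calls.tsv")), progress = FALSE)
    jsonlite::write_json(
      list(seed = fit$null_dist$seed, n_null = length(fit$null_dist$null_spms),
           tau = fit$null_dist$threshold, percentile = fit$null_dist$percentile,
           percentile_convention = "linear interpolation (quantile type 7)"),
      file.path(out_dir, paste0(sp, "_null.json")),
      auto_unbox = TRUE, digits = NA
    )
    readr::write_lines(dendrogram_newick(trees$samples[[sp]]),
                       file.path(out_dir, paste0(sp, "_sample_tree.nwk")))
  }
  readr::write_tsv(categories, file.path(out_dir, "categories.tsv"), progress = FALSE)
  readr::write_tsv(correlations, file.path(out_dir, "interspecies_spearman.tsv"),
                   progress = FALSE)
  readr::write_lines(dendrogram_newick(trees$profile_tree),
                     file.path(out_dir, "spm_profile_tree.nwk"))
  if (!is.null(enrichment)) {
    for (r in names(enrichment)) {
      if (!is.null(enrichment[[r]])) {
        readr::write_tsv(enrichment[[r]],
                         file.path(out_dir, paste0("enrichment_", r, ".tsv")),
                         progress = FALSE)
      }
    }
  }
  if (!is.null(scores)) {
    readr::write_tsv(scores$per_species, file.path(out_dir, "recovery_per_species.tsv"),
                     progress = FALSE)
    if (!is.null(scores$category)) {
      readr::write_tsv(scores$category, file.path(out_dir, "recovery_category.tsv"),
                       progress = FALSE)
    }
  }

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = as.integer(seed),
    reference_species = reference,
    stages = env$stages,
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    fits = fits, categories = categories, trees = trees,
    correlations = correlations, enrichment = enrichment,
    scores = scores, truth = ds$truth, manifest = manifest,
    out_dir = out_dir
  ))
}
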