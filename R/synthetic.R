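#' Configuration for the synthetic multi-species dataset generator
#'
#' Describes a three-species, three-platform heart expression study on the
#' log2 scale: a shared baseline per ancestral gene, additive region effects
#' on planted region-specific genes, per-individual and per-measurement
#' Gaussian noise, additive + multiplicative platform distortions,
#' platform-specific gene dropout (a gene simply absent from one array, as
#' happens with real chips), and a mostly one-to-one ortholog graph with a
#' configurable fraction of one-to-two families.
#'
#' Planted genes come in conservation categories: `common` ancestors carry
#' the same region effect in all species, `pairwise` ancestors in one species
#' pair, `selective` ancestors in a single species. Per region each species
#' therefore carries `n_common + (n_species - 1) * n_pairwise + n_selective`
#' planted genes (50 with the defaults).
#'
#' @param species Species labels; the first is the reference for
#'   cross-species truth.
#' @param platform_shift,platform_scale Named additive shift / multiplicative
#'   scale applied to each species' log2 values (platform location/scale).
#' @param dropout Named per-species probability that a gene is absent from
#'   that platform.
#' @param regions Region labels (default LA, V, SA).
#' @param replicates Samples per region: a single count or a named per-region
#'   vector (e.g. `c(LA = 4, V = 2, SA = 4)`).
#' @param n_genes Number of ancestral genes.
#' @param baseline_mean,baseline_sd Normal distribution of ancestral baseline
#'   log2 expression.
#' @param species_sd SD of the per-species deviation from the ancestral
#'   baseline.
#' @param individual_sd SD of the per-sample (individual) random shift.
#' @param sigma Within-region measurement noise SD (log2 units).
#' @param delta Planted region effect (log2 units) added in the target
#'   region.
#' @param n_common,n_pairwise,n_selective Planted ancestors per region:
#'   common to all species / per species pair / per single species.
#' @param multi_frac Fraction of ancestors represented by two genes
#'   (one-to-two ortholog families) in each species.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(species = c("human", "mouse", "rat"),
                             platform_shift = c(human = 0, mouse = 1.5, rat = -1),
                             platform_scale = c(human = 1, mouse = 1.1, rat = 0.9),
                             dropout = c(human = 0, mouse = 0.02, rat = 0.02),
                             regions = c("LA", "V", "SA"),
                             replicates = 4,
                             n_genes = 5000,
                             baseline_mean = 6, baseline_sd = 2,
                             species_sd = 0.5, individual_sd = 0.2,
                             sigma = 0.5, delta = 4,
                             n_common = 10, n_pairwise = 5, n_selective = 30,
                             multi_frac = 0.05) {
  cfg <- list(
    species = species, platform_shift = platform_shift,
    platform_scale = platform_scale, dropout = dropout, regions = regions,
    replicates = replicates, n_genes = n_genes,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    species_sd = species_sd, individual_sd = individual_sd,
    sigma = sigma, delta = delta,
    n_common = n_common, n_pairwise = n_pairwise, n_selective = n_selective,
    multi_frac = multi_frac
  )
  for (nm in c("platform_shift", "platform_scale", "dropout")) {
    v <- cfg[[nm]]
    if (length(v) == 1 && is.null(names(v))) {
      cfg[[nm]] <- setNames(rep(v, length(species)), species)
    }
    if (!all(species %in% names(cfg[[nm]]))) {
      abort(sprintf("%s must name every species", nm))
    }
  }
  if (any(cfg$dropout < 0 | cfg$dropout > 1)) abort("dropout must lie in [0, 1]")
  if (cfg$multi_frac < 0 || cfg$multi_frac > 1) abort("multi_frac must lie in [0, 1]")
  counts <- c(cfg$n_common, cfg$n_pairwise, cfg$n_selective)
  if (any(counts < 0)) abort("planted counts must be >= 0")
  if (any(counts > 0) && cfg$delta <= 0) abort("delta must be > 0 when genes are planted")
  if (length(cfg$replicates) == 1 && is.null(names(cfg$replicates))) {
    cfg$replicates <- setNames(rep(cfg$replicates, length(regions)), regions)
  }
  if (!all(regions %in% names(cfg$replicates))) abort("replicates must name every region")
  if (any(cfg$replicates < 1)) abort("need >= 1 replicate per region")
  n_pairs <- choose(length(species), 2)
  n_slots <- length(regions) *
    (cfg$n_common + n_pairs * cfg$n_pairwise + length(species) * cfg$n_selective)
  if (n_slots > cfg$n_genes) abort("planted counts exceed n_genes")
  structure(cfg, class = "synthetic_config")
}

# Does a comma-separated species set contain `sp`?
set_has <- function(set_str, sp) {
  vapply(strsplit(set_str, ",", fixed = TRUE), function(x) sp %in% x, logical(1))
}

species_prefixes <- function(species) {
  setNames(substr(species, 1, 3), species)
}

# Plan which ancestors are planted, in which region, for which species set.
plant_plan <- function(cfg) {
  species <- cfg$species
  pairs <- if (length(species) >= 2) combn(species, 2, simplify = FALSE) else list()
  units <- list()
  for (r in cfg$regions) {
    if (cfg$n_common > 0) {
      units[[length(units) + 1]] <- list(region = r, category = "common_all",
                                         set = species, n = cfg$n_common)
    }
    for (pr in pairs) {
      if (cfg$n_pairwise > 0) {
        units[[length(units) + 1]] <- list(region = r, category = "pairwise",
                                           set = pr, n = cfg$n_pairwise)
      }
    }
    for (s in species) {
      if (cfg$n_selective > 0) {
        units[[length(units) + 1]] <- list(region = r, category = "selective",
                                           set = s, n = cfg$n_selective)
      }
    }
  }
  units
}

#' Generate a synthetic multi-species expression dataset with ground truth
#'
#' Draws, under one seeded generator (consumed in documented order: ancestor
#' baselines, planted-gene assignment, then per species gene effects, sample
#' effects, noise and dropout), a complete cross-platform study: per-species
#' log2 expression tables and sample metadata, pairwise ortholog tables, and
#' the planted truth. Values are
#' `scale * (baseline + delta * planted + individual + noise) + shift`,
#' truncated at 0.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; identical config + seed reproduce the dataset
#'   exactly.
#' @return List with elements `expression` (named list of tibbles),
#'   `metadata` (named list of tibbles), `orthologs` (list of ortholog
#'   tables), `truth` (list: `per_species` tibbles of planted genes with a
#'   `present` flag, `reference` tibble of effective cross-species categories
#'   on reference gene ids, `reference_species`), `config`, `seed`.
#' @export
generate_dataset <- function(cfg = synthetic_config(), seed) {
  if (missing(seed)) abort("an integer seed is required")
  withr::with_seed(as.integer(seed), generate_dataset_impl(cfg, as.integer(seed)))
}

generate_dataset_impl <- function(cfg, seed) {
  species <- cfg$species
  regions <- cfg$regions
  anc <- sprintf("g%05d", seq_len(cfg$n_genes))
  baseline <- setNames(rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd), anc)

  units <- plant_plan(cfg)
  pool <- sample(anc)
  taken <- 0
  plan <- list()
  for (u in units) {
    ids <- pool[(taken + 1):(taken + u$n)]
    taken <- taken + u$n
    plan[[length(plan) + 1]] <- tibble(
      ancestor = ids, region = u$region, category = u$category,
      planted_set = paste(sort(u$set), collapse = ",")
    )
  }
  plan <- if (length(plan) > 0) bind_rows(plan) else
    tibble(ancestor = character(), region = character(),
           category = character(), planted_set = character())

  pref <- species_prefixes(species)
  expression <- list()
  metadata <- list()
  genes_by_species <- list()
  present_by_species <- list()

  for (sp in species) {
    dup <- runif(cfg$n_genes) < cfg$multi_frac
    gene_anc <- c(anc, anc[dup])
    dup_ids <- if (any(dup)) paste0(pref[[sp]], "_", anc[dup], "b") else character(0)
    gene_id <- c(paste0(pref[[sp]], "_", anc), dup_ids)
    ord <- order(gene_id)
    gene_anc <- gene_anc[ord]
    gene_id <- gene_id[ord]
    ng <- length(gene_id)
    b <- baseline[gene_anc] + rnorm(ng, 0, cfg$species_sd)

    reps <- cfg$replicates[regions]
    sample_region <- rep(regions, times = reps)
    sample_id <- unlist(lapply(regions, function(r) {
      sprintf("%s_%s_%d", pref[[sp]], r, seq_len(cfg$replicates[[r]]))
    }))
    ns <- length(sample_id)
    indiv <- rnorm(ns, 0, cfg$individual_sd)

    # planted effect indicator: gene x sample
    plant_sp <- plan |> filter(set_has(.data$planted_set, sp))
    eff <- matrix(0, nrow = ng, ncol = ns)
    if (nrow(plant_sp) > 0) {
      for (i in seq_len(nrow(plant_sp))) {
        rows <- which(gene_anc == plant_sp$ancestor[i])
        cols <- which(sample_region == plant_sp$region[i])
        eff[rows, cols] <- cfg$delta
      }
    }
    noise <- matrix(rnorm(ng * ns, 0, cfg$sigma), nrow = ng)
    vals <- cfg$platform_scale[[sp]] *
      (b + eff + matrix(indiv, nrow = ng, ncol = ns, byrow = TRUE) + noise) +
      cfg$platform_shift[[sp]]
    vals <- pmax(vals, 0)
    dimnames(vals) <- list(gene_id, sample_id)

    keep <- runif(ng) >= cfg$dropout[[sp]]
    expression[[sp]] <- expr_tibble(vals[keep, , drop = FALSE])
    metadata[[sp]] <- tibble(
      sample_id = sample_id, species = sp, region = sample_region,
      individual_id = sample_id, platform_id = paste0(sp, "_platform")
    )
    genes_by_species[[sp]] <- tibble(ancestor = gene_anc, gene_id = gene_id)
    present_by_species[[sp]] <- setNames(keep, gene_id)
  }

  orthologs <- list()
  species_pairs <- if (length(species) >= 2) combn(species, 2, simplify = FALSE) else list()
  for (pr in species_pairs) {
    a <- genes_by_species[[pr[1]]]
    b2 <- genes_by_species[[pr[2]]]
    tab <- a |>
      inner_join(b2, by = "ancestor", relationship = "many-to-many",
                 suffix = c("_x", "_y")) |>
      select(x_gene = "gene_id_x", y_gene = "gene_id_y") |>
      arrange(.data$x_gene, .data$y_gene)
    orthologs[[paste(pr, collapse = "_")]] <- ortholog_table(tab, pr[1], pr[2])
  }

  truth_per_species <- list()
  for (sp in species) {
    gb <- genes_by_species[[sp]]
    tp <- plan |>
      filter(set_has(.data$planted_set, sp)) |>
      inner_join(gb, by = "ancestor", relationship = "many-to-many") |>
      mutate(present = unname(present_by_species[[sp]][.data$gene_id])) |>
      select("gene_id", "ancestor", "region", "category", "planted_set", "present")
    truth_per_species[[sp]] <- tp
  }

  reference <- species[1]
  truth_reference <- reference_truth(plan, genes_by_species, present_by_species,
                                     species, reference)

  list(
    expression = expression,
    metadata = metadata,
    orthologs = orthologs,
    truth = list(per_species = truth_per_species,
                 reference = truth_reference,
                 reference_species = reference),
    config = cfg,
    seed = seed
  )
}

# Effective cross-species category of each planted reference gene after
# dropout: a species counts as carrying the ancestor's effect only if at
# least one of its copies survived its platform.
reference_truth <- function(plan, genes_by_species, present_by_species,
                            species, reference) {
  if (nrow(plan) == 0) {
    return(tibble(gene_id = character(), region = character(),
                  category = character(), species_set = character()))
  }
  eff_set <- vapply(seq_len(nrow(plan)), function(i) {
    planted <- strsplit(plan$planted_set[i], ",", fixed = TRUE)[[1]]
    carried <- planted[vapply(planted, function(sp) {
      ids <- genes_by_species[[sp]]$gene_id[genes_by_species[[sp]]$ancestor == plan$ancestor[i]]
      any(present_by_species[[sp]][ids])
    }, logical(1))]
    paste(sort(carried), collapse = ",")
  }, character(1))
  out <- plan |>
    mutate(species_set = eff_set) |>
    filter(set_has(.data$species_set, reference)) |>
    mutate(category = case_when(
      lengths(strsplit(.data$species_set, ",")) == length(species) ~ "common_all",
      lengths(strsplit(.data$species_set, ",")) == 1 ~ "selective",
      TRUE ~ "pairwise"
    ))
  gb <- genes_by_species[[reference]]
  pres <- present_by_species[[reference]]
  out |>
    inner_join(gb, by = "ancestor", relationship = "many-to-many") |>
    filter(pres[.data$gene_id]) |>
    select("gene_id", "region", "category", "species_set")
}

#' Score recovery of planted truth
#'
#' Compares specific-gene calls and cross-species categories against the
#' planted truth of [generate_dataset()]. Per species: sensitivity
#' `TP / (TP + FN)` and observed FDR `FP / (TP + FP)` over (gene, region)
#' calls, counting only genes present on the species' platform. Category
#' accuracy is scored over reference-indexed planted genes that were called
#' specific in their true region (misses are charged to sensitivity, not to
#' classification), comparing both the category label and the agreeing
#' species set.
#'
#' @param calls_by_species Named list of calls tibbles (or `spm_fit`s).
#' @param categories Reference-indexed classification from
#'   [categorize_specific_sets()], or `NULL` to skip category scoring.
#' @param truth The `truth` element of [generate_dataset()].
#' @return List: `per_species` tibble (`species`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `fdr`, `fdr_defined`), `category` tibble (`accuracy`,
#'   `n_evaluated`), `confusion` contingency table (truth x predicted).
#' @export
score_recovery <- function(calls_by_species, categories, truth) {
  per_species <- imap(calls_by_species, function(calls, sp) {
    if (inherits(calls, "spm_fit")) calls <- calls$calls
    called <- calls |> filter(.data$is_specific) |> distinct(.data$gene_id, .data$region)
    tr <- truth$per_species[[sp]] |> filter(.data$present)
    truth_keys <- paste(tr$gene_id, tr$region)
    call_keys <- paste(called$gene_id, called$region)
    tp <- sum(call_keys %in% truth_keys)
    fp <- length(call_keys) - tp
    fn <- length(truth_keys) - tp
    tibble(
      species = sp, tp = tp, fp = fp, fn = fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
      fdr_defined = tp + fp > 0
    )
  }) |> bind_rows()

  category <- NULL
  confusion <- NULL
  if (!is.null(categories)) {
    evaled <- truth$reference |>
      inner_join(categories, by = c("gene_id", "region"),
                 suffix = c("_truth", "_pred"))
    if (nrow(evaled) > 0) {
      match_ok <- evaled$category_truth == evaled$category_pred &
        evaled$species_set_truth == evaled$species_set_pred
      category <- tibble(accuracy = mean(match_ok), n_evaluated = nrow(evaled))
      confusion <- table(truth = evaled$category_truth, predicted = evaled$category_pred)
    } else {
      category <- tibble(accuracy = NA_real_, n_evaluated = 0L)
    }
  }
  list(per_species = per_species, category = category, confusion = confusion)
}

#' Generate a small count table to exercise the TPM path
#'
#' Poisson-lognormal counts with lognormal gene lengths: a thin count-scale
#' companion to the log2-scale generator, for testing [compute_tpm()].
#'
#' @param n_genes,n_samples Table dimensions.
#' @param seed Integer seed.
#' @return List with `counts` (tibble) and `gene_lengths` (tibble).
#' @export
generate_count_table <- function(n_genes = 200, n_samples = 6, seed) {
  if (missing(seed)) abort("an integer seed is required")
  withr::with_seed(as.integer(seed), {
    genes <- sprintf("g%04d", seq_len(n_genes))
    len <- round(exp(rnorm(n_genes, log(1500), 0.6))) + 200
    mu <- exp(rnorm(n_genes, log(50), 1))
    counts <- matrix(stats::rpois(n_genes * n_samples, mu), nrow = n_genes,
                     dimnames = list(genes, sprintf("s%02d", seq_len(n_samples))))
    list(
      counts = expr_tibble(counts),
      gene_lengths = tibble(gene_id = genes, length = as.numeric(len))
    )
  })
}
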