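# cardiospm

Cross-species, cross-platform identification of heart region-specific genes
with the **specificity measure (SPM)**.

## The problem

Bulk expression data for the same organ often come from incompatible
platforms: one species measured on a bead array, another on a two-color
array, a third by RNA-seq. Absolute intensities, medians and dynamic ranges
differ, so expression values cannot be compared across species directly.
Region *specificity*, however, can: for each gene the vector of region-mean
expression values is reduced to a dimensionless statistic that survives
per-platform location and scale differences.

For gene *g* with region-mean vector *m<sub>g</sub>* = (m<sub>g,1</sub>, …,
m<sub>g,R</sub>) over regions such as left atrium (LA), ventricle (V; left
and right pooled) and sinoatrial node (SA):

```
SPM(g, r) = m_{g,r} / ||m_g||_2
```

the cosine between the mean vector and region *r*'s axis. SPM lies in
[0, 1], the squared values sum to 1 per gene, and SPM = 1 means expression
confined to one region.

A gene is called **region-specific** when both gates pass:

1. `SPM(g, r) > tau`, where `tau` is the 95th percentile of a permutation
   null built from one random region-label permutation per gene (null SPM
   values pooled over all genes and regions of the dataset);
2. the one-way ANOVA of expression across regions gives a
   Benjamini–Hochberg adjusted p-value below 0.05.

Calls from several species are then connected through many-to-many ortholog
tables (one-to-many counterpart values averaged) and classified as
**common to all species**, **pairwise**, or **species-selective** — the
distinction that separates conserved regional programs (e.g. a
pacemaker-region transcription factor specific in every species) from
platform- or species-restricted markers. The package also provides the
supporting machinery: per-platform normalization (log2, median alignment,
90-percentile normalization, probe collapse by maximum, TPM), hierarchical
clustering of samples and of cross-species SPM profiles under the
1 − Spearman distance, hypergeometric over-representation analysis, and a
fully seeded synthetic-data generator with planted ground truth.

## Worked example

Simulate a three-species, three-platform study with planted region-specific
genes, fit one species, and classify calls across species:

```r
library(cardiospm)

cfg <- synthetic_config(n_genes = 1000, n_common = 5, n_pairwise = 3, n_selective = 8)
ds  <- generate_dataset(cfg, seed = 42)

fit <- fit_region_specificity(ds$expression$human, ds$metadata$human,
                              expressed_threshold = 1, seed = 43)
fit
#> Region-specificity fit: 1038 genes x 12 samples, regions LA/V/SA
#>   tau = 0.6250 (p95 of permutation null), alpha = 0.05
#>   60 specific gene-region calls

head(specific_gene_table(fit), 5)
#> # A tibble: 5 x 5
#>   gene_id    region   spm      adj_p multi_region
#>   <chr>      <chr>  <dbl>      <dbl> <lgl>
#> 1 hum_g00985 LA     0.874 0.0000439  FALSE
#> 2 hum_g00705 LA     0.851 0.0000439  FALSE
#> 3 hum_g00876 LA     0.848 0.00000649 FALSE
#> 4 hum_g00923 LA     0.839 0.000275   FALSE
#> 5 hum_g00412 LA     0.803 0.000501   FALSE
```

`tau = 0.625` is the dataset's permutation-null threshold: only genes whose
SPM exceeds what label shuffling produces (95th percentile) can be called,
and 60 gene–region pairs pass both gates here. Classifying all three
species against the planted truth:

```r
fits <- lapply(names(ds$expression), function(sp)
  fit_region_specificity(ds$expression[[sp]], ds$metadata[[sp]],
                         expressed_threshold = 1, seed = 43))
names(fits) <- names(ds$expression)
cats <- categorize_specific_sets(lapply(fits, `[[`, "calls"),
                                 ds$orthologs, reference = "human")
dplyr::count(cats, category)
#>   category       n
#> 1 common_all    14
#> 2 pairwise      20
#> 3 selective     26

score_recovery(fits, cats, ds$truth)$per_species
#>   species    tp    fp    fn sensitivity    fdr
#> 1 human      60     0     0           1 0
#> 2 mouse      63     0     0           1 0
#> 3 rat        58     1     0           1 0.0169
```

Every planted gene is recovered (sensitivity 1) with at most one false call
per species. `run_pipeline()` executes the same stages end to end — from
simulation or from expression/metadata/ortholog TSVs — and writes SPM
tables, calls, null-distribution summaries, category tables, Newick
dendrograms and a run manifest to an output directory, reproducibly for a
given config and seed.

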