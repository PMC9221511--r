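---
title: "Region-specificity analysis with SPM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-specificity analysis with SPM: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiospm)
```

## The statistical model

The package targets a recurring situation in comparative transcriptomics:
expression of the same organ measured in several species on several
platforms (bead arrays, two-color arrays, RNA-seq), where absolute
intensities are incomparable but *within-dataset regional contrast* is
informative. All statistics operate on log2-scale values — `log2(x + 1)` of
intensities or TPM — so that values are non-negative and additive shifts
correspond to multiplicative intensity changes.

For gene $g$, let $m_{g,r}$ be the arithmetic mean of its log2 expression
over the samples of region $r$ (ventricular samples are pooled into one
region $V$ before any statistic; regions outside the declared set, such as
the right atrium, are excluded from the specificity analysis but remain
available for sample clustering). The specificity measure is

$$\mathrm{SPM}_{g,r} = \frac{m_{g,r}}{\lVert m_g \rVert_2},$$

the cosine between the region-mean vector and the axis of region $r$. We
read the normalizer as the Euclidean norm (not the L1 sum): only the L2
reading makes SPM the cosine of an angle, bounded in $[0,1]$ with
$\sum_r \mathrm{SPM}_{g,r}^2 = 1$, which is what makes values comparable
across genes, platforms and species. A gene whose mean vector is exactly
zero has no direction and is excluded rather than assigned a value.

A gene is called specific for region $r$ when two independent gates both
pass:

* **Magnitude gate** — $\mathrm{SPM}_{g,r} > \tau$, where $\tau$ is the
  95th percentile of a permutation null: for each gene, one uniformly
  random permutation of the sample-to-region assignment is drawn, region
  means and all region SPM values are recomputed, and the null values of
  all genes and all regions are pooled into a single distribution per
  dataset. Pooling (rather than per-region thresholds) reflects that the
  threshold characterizes the dataset's noise geometry, not a particular
  region; one threshold per dataset is also what a single dotted cutoff
  line on a per-species SPM axis corresponds to.
* **Evidence gate** — the one-way fixed-effects ANOVA of expression across
  regions, with Benjamini–Hochberg adjustment across genes, gives
  adjusted $p < \alpha$ (default 0.05).

The two gates fail in different ways: SPM alone would call genes whose
apparent specificity is noise on a tiny denominator; ANOVA alone would call
any reproducible difference, however mild its regional concentration.

When $\tau \ge 1/\sqrt{2}$, at most one region per gene can exceed the
threshold (two cosines cannot both exceed $1/\sqrt 2$). The calibrated
thresholds produced by the permutation null on realistic noise are ~0.6,
slightly below that bound, so multi-region qualification is possible in
principle; such genes are flagged (`multi_region`) and the region of
maximal SPM reported in the per-gene summary.

## Cross-species classification

Orthology is taken as given (Biomart-style many-to-many pair tables).
Mapping is directional: the x-species indexes the comparison and, when one
x gene corresponds to several y genes, the y values are averaged. Because
averaging makes the map asymmetric, the direction is always explicit; for
rodent–rodent comparisons the caller chooses the index species.

A gene specific for region $r$ in the index species is **common to all
species** if in *every* other species at least one ortholog is specific for
the same region; **species-selective** if no ortholog in any other species
agrees; **pairwise** otherwise. The any-ortholog reading is the weakest
consistent interpretation of "its ortholog is also identically
region-specific" for one-to-many families; the agreeing species set is
recorded per gene so a stricter all-ortholog variant can be audited from
the output. Genes lacking orthologs in some species cannot be common to all
species by construction.

Interspecies similarity itself is summarized by Spearman's rank correlation
of ortholog-paired region means — rank-based because cross-platform
intensity scales are not comparable — and clustering (of samples within a
platform, and of the $species \times region$ SPM profile vectors across
platforms) uses the $1 - \rho_{Spearman}$ distance with average (UPGMA)
linkage. The linkage is a declared default, not an inference from any
external source, and is configurable in spirit: the exported functions
return ordinary `hclust` trees. Tie-breaking follows the deterministic
behavior of the agglomeration given a fixed input order; profile and sample
orders are fixed by the input tables, so runs are reproducible.

## Enrichment

Over-representation uses the one-sided hypergeometric upper tail
(equivalently one-sided Fisher), with all counts computed after
intersecting term sets, query and universe with the declared background.
The default background is the set of genes that entered the specificity
analysis of the same dataset — the natural universe, since only those genes
could have been called. The background is exposed as an argument because
reasonable alternatives exist (e.g. genes analyzable in all species).
Annotations are taken as given (GMT or long two-column tables); no GO-graph
propagation is performed. Transcription factors are defined by membership
in GO:0003700 (DNA-binding transcription factor activity), and ranked
within a gene set by SPM magnitude with lexicographic tie-breaking.

## Normalization conventions

* **Median alignment** and **90-percentile normalization** are additive
  shifts on the log2 scale: each sample is shifted so that its median (or
  90th percentile) equals the grand median of the per-sample statistics.
  Additive log2 shifts are scale factors in linear space, preserve the
  rank order within each sample, and cannot manufacture regional contrast.
* **Percentiles** use linear interpolation between order statistics
  (`quantile` type 7) everywhere — in normalization and in the permutation
  threshold — so the two subsystems share a single convention.
* After an additive shift, values that were near zero can become slightly
  negative; since SPM requires non-negative means the pipeline floors
  normalized matrices at zero, mirroring the `log2(x + 1)` floor.
* **Probe collapse** keeps, per gene and sample, the maximum signal over
  the gene's probes; probes absent from the probe map are dropped and
  counted rather than passed through.
* **Expression filtering** keeps genes exceeding a per-dataset threshold in
  at least one sample, with a strict inequality. The threshold is a
  platform property (low for log2 TPM, higher for array intensities) and is
  applied after the `log2(x + 1)` transform, i.e. after the pseudocount.
* **TPM** divides counts by gene length in kilobases and rescales each
  sample to $10^6$; all-zero samples stay all-zero with a warning rather
  than producing NaN.

## The synthetic-data generator

Because the statistics above are scale-free, they can be validated on
simulated data whose ground truth is known exactly. The generator encodes
the study conditions as defaults and draws, from one seeded generator in a
documented order (ancestor baselines, planted-gene assignment, then per
species: gene-level deviations, duplication, sample effects, measurement
noise, dropout):

$$x_{g,s} = c_p\,\bigl(b_g + \delta\,[g\text{ planted for region}(s)] +
u_{\mathrm{ind}(s)} + \varepsilon_{g,s}\bigr) + d_p,\quad
x_{g,s} \leftarrow \max(x_{g,s}, 0)$$

with ancestral baseline $b \sim N(6, 2^2)$ log2 units (a realistic bulk
log2 expression distribution) plus a per-species deviation
$N(0, 0.5^2)$, individual effects $u \sim N(0, 0.2^2)$, measurement noise
$\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.5$, region effect
$\delta = 4$ log2 units, platform scale $c_p \in \{1, 1.1, 0.9\}$ and shift
$d_p \in \{0, +1.5, -1\}$ for the RNA-seq-like, bead-array-like and
two-color-array-like platforms, and per-platform gene dropout
(0, 2%, 2%) emulating genes simply absent from an array design. The
ortholog graph is one-to-one except for a 5% fraction of one-to-two
families. Per region, planted ancestors comprise 10 common to all species,
5 per species pair and 30 per single species — 50 planted genes per region
per species. Three regions (LA, V, SA) with 4 replicates each reflect a
typical design; replicate counts are configurable per region for uneven
designs.

Truth bookkeeping accounts for dropout: if a commonly planted ancestor
loses its copy on one platform, its *effective* category is downgraded
(common → pairwise), because no method could recover a gene a platform
never measured — exactly the situation of a canonical marker missing from
one array. Recovery scoring conditions category accuracy on the reference
gene being called in its true region, so detection failures are charged to
sensitivity and not double-counted as classification errors.

What the generator does **not** emulate: probe-level microarray artifacts,
count-level RNA-seq noise (a thin Poisson-lognormal count mode exists only
to exercise the TPM path), heavy-tailed inter-individual variability in
humans, correlated gene modules, and compositional effects. Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under the declared noise model — not that any particular
biological dataset would yield the same gene lists.

## Numerical choices and degenerate inputs

* ANOVA is computed by the sum-of-squares decomposition vectorized across
  genes (the test suite checks it against R's model fitter to $10^{-10}$).
  Zero total variance yields $p = 1$ with a degenerate flag (no evidence of
  regional difference); zero within-group variance with unequal means
  yields $F = \infty$, $p = 0$.
* The permutation draws one label permutation per gene, implemented as a
  row-wise value permutation (equivalent, since region multiplicities are
  preserved) under a single seeded generator consumed in gene order. Two
  runs with the same seed are identical; bit-level agreement across
  *different implementations* of the generator is not promised — all
  downstream checks are statistical.
* BH adjustment, hypergeometric tails, Spearman correlation and
  hierarchical clustering delegate to R's reference implementations behind
  the package's interfaces; each is verified in the test suite against an
  independent hand-written oracle (step-up double loop, combinatorial
  summation, brute-force UPGMA).
* Constant columns make correlation undefined: sample clustering rejects
  them by sample id rather than silently dropping, and z-scoring a
  zero-variance SPM column returns zeros with a warning.

## Problem sizes used in validation

The shipped validation uses 10,000-gene exchangeable-null datasets (20
seeds) for threshold calibration, the 5,000-gene default scenario (10
seeds) for recovery, a 2,000-gene conserved-program scenario (10 seeds) for
cross-platform profile clustering, and 400–500-gene configurations for the
byte-identity and stage-orchestration checks. These sizes give stable
Monte-Carlo estimates (e.g. the null exceedance rate is estimated from
30,000 pooled SPM values per seed) while keeping a full validation run in
the minutes range on a laptop.

For the conserved-program clustering scenario the planted mix is shifted
toward common ancestors (30 common, 5 per pair, 10 selective per region):
cross-platform clustering of SPM profiles asks whether *shared* regional
programs dominate platform differences, so the scenario plants a
predominantly conserved regional identity — the biological situation the
analysis is designed to reveal. With region effects of 4 log2 units against
platform shifts of ±1.5, the nine species-region profiles cluster by
region, not by platform.

## Known limitations

* The permutation null uses one permutation per gene; with few samples the
  number of distinct label permutations is modest, and $\tau$ inherits
  Monte-Carlo noise of order $1/\sqrt{G}$ across datasets.
* Averaging one-to-many ortholog values blurs paralog-specific expression;
  the any-ortholog agreement rule is permissive by design.
* The ANOVA is a fixed-effects one-way model; individual effects are not
  modeled as random effects, matching the simplicity of the original
  procedure rather than the state of the art in mixed modeling.
* SPM compares *relative* regional allocation; a gene uniformly expressed
  everywhere is never specific regardless of its absolute level, and a
  lowly expressed gene can be highly specific — the expression filter is
  the only absolute-level gate.
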