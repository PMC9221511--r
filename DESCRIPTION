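Package: cardiospm
Title: Cross-Species Cardiac Region-Specificity Analysis with the SPM Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies heart region-specific genes across species and
    expression platforms using the specificity measure (SPM), the cosine
    between a gene's region-mean expression vector and a region axis.
    Provides per-platform normalization (log2, median alignment, percentile
    normalization, probe collapse, TPM), SPM computation with a
    permutation-derived null threshold gated by one-way ANOVA with
    Benjamini-Hochberg correction, many-to-many ortholog mapping to classify
    species-common versus species-selective region markers, hierarchical
    clustering of samples and of SPM profiles (1 - Spearman distance),
    hypergeometric over-representation analysis, and a synthetic multi-species
    multi-platform data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
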