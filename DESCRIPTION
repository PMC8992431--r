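Package: rootqtl
Title: Root Phenomics to Field: Spatial Adjustment, Mixed-Model GWAS,
    LD-Block QTL Delimitation and Environment Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis chain linking platform-phenotyped root-system
    traits of inbred cereal panels to field agronomic performance.
    Plot-level phenotyping-platform measurements are adjusted for spatial
    heterogeneity with a tensor-product P-spline mixed model (random
    blocks, temperature-sum covariate) yielding genotype BLUEs and
    generalized heritabilities; single-locus mixed-model association
    (EMMA: variance components estimated once under the null, then fixed
    for per-SNP GLS tests) with a VanRaden kinship matrix and optional
    principal-component structure correction; Benjamini-Hochberg FDR
    selection of SNPs; QTL interval delimitation by UPGMA clustering of
    linkage-disequilibrium blocks cut at a data-derived critical R2
    (99.9th percentile of inter-chromosome r2, optionally corrected for
    relatedness by GLS whitening); QTL overlap and colocalization rules;
    and environment integration (phenology correction of yield traits,
    effective-number-of-tests Bonferroni control, per-environment QTL
    effects regressed on environmental covariates, registration-era
    trend tests). A synthetic-data generator emulates the statistical
    structure of such studies (haplotype-block LD decay, subpopulation
    structure, greenhouse spatial trends, genotype-by-environment
    reaction norms) and supplies ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
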