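---
title: "From rhizotube phenotypes to field QTLs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From rhizotube phenotypes to field QTLs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootqtl)
```

rootqtl implements an analysis chain that links root-system-architecture
(RSA) traits measured on young cereal plants in a greenhouse phenotyping
platform to agronomic performance measured in multi-environment field
trials. The chain has five stages — spatial adjustment, mixed-model
association, QTL delimitation, colocalization, and environment
integration — plus a synthetic-data generator that reproduces the
statistical structure those stages assume and supplies ground truth for
recovery tests. This vignette documents the models, the tunable
parameters, the numerical choices, and what the tests do and do not
establish.

## Spatial adjustment of platform data

Rhizotube platforms phenotype hundreds of inbred lines with essentially
one plot (one rhizotube) per line per experiment, plus a handful of check
varieties replicated once per block. Greenhouse conditions drift smoothly
in space, so raw plot values confound genotype and position. The model
fitted by `fit_spatial_model()` is

    trait ~ intercept + genotype + beta * temperature-sum
            + block (random) + f(row, col)

where `f` is a tensor-product penalized B-spline surface (default 8 x 8
marginal basis, reduced automatically when the plot count cannot support
it) and all smoothing/variance parameters are estimated by REML through
mgcv. The temperature sum is the accumulated degree-days above a 0 °C
baseline at the plot; it is centered so genotype effects absorb the mean.
With genotype fixed, the adjusted means (BLUEs) are the genotype
predictions at the average covariate with the block and surface
components excluded; adding a constant to every plot shifts every BLUE by
exactly that constant. With genotype random, `generalized_heritability()`
returns `H2 = ED_g / (n_g - 1)`, where `ED_g` is the effective dimension
(summed effective degrees of freedom) of the genotype component — the
effective-dimension heritability used with P-spline spatial models.

Three experiments are adjusted separately and combined by precision
weighting (`1/se^2`) in `trait_blues()`; the per-trait heritability is
the mean across experiments. Pooling all experiments in a single model is
a defensible alternative; separate fits keep the per-experiment surfaces
independent and are what the precision-weighted combination assumes.

Outlier handling (`filter_outliers()`) is rule-based: plots with any
biomass below 0.5 g are failed plants and removed; after a provisional
fit, plots with |standardized residual| > 4 are removed (the threshold is
configurable — it replaces a per-trait visual call that cannot be
reproduced programmatically). The provisional fit uses a *random*
genotype effect: with one plot per genotype a fixed effect would absorb
the plot's own aberration, so residual-based detection only has power for
replicated material (checks, or `n_rep > 1`); this limitation is
inherent, not an implementation artifact. Genotype-level screens on
adjusted means (`filter_genotype_bounds()`) implement upper bounds such
as convex hull > 40,000 or rooting depth > 400.

Sensor interpolation (`interpolate_sensors()`) defaults to
inverse-distance weighting (power 2), which is exact at sensor positions;
ordinary kriging with an exponential variogram fitted to the empirical
semivariances is available via `method = "kriging"`. Both report the
leave-one-sensor-out RMSE. IDW is slightly biased at the convex-hull
boundary of the sensor network; with a dense network both methods keep
the cross-validation error below a few percent of the field's range.
Growth trajectories are smoothed by a 5-point local linear regression
(`smooth_trajectories()`), and trait values are read off the smoothed
curve at a target day (default day 10); series shorter than the window
fall back to a single global linear fit and are flagged.

## Mixed-model association

Association uses the standard single-locus mixed model
`y = X beta + u + e`, `Var(u) = K sigma2_G`, `Var(e) = I sigma2_e`, with
the VanRaden kinship `K = V V' / (2 sum p_i (1 - p_i))` computed from the
column-centered dosage matrix. Marker QC (`qc_markers()`) imputes missing
dosages with the observed allele frequency, recodes so the counted allele
is the minor one (the major allele is the reference), collapses exact
duplicates keeping the first in map order, and drops markers with minor
allele count below 20.

The EMMA scheme estimates the variance components once, under the null:
`K` is eigendecomposed, the model rotated onto the eigenbasis, and the
REML profile maximized over the single ratio `lambda = sigma2_G /
sigma2_e` by 1-D optimization (`fit_null_model()`). Each SNP is then
tested by GLS with the covariance fixed (`test_snps()`): on the whitened
data the SNP coefficient is a least-squares estimate given the fixed
covariates, with a Wald t-test on `n - rank(X) - 1` degrees of freedom.
The residual scale is re-estimated per SNP on the whitened model — a
deliberate choice that makes the `K = I` case collapse exactly onto
ordinary least squares, which the tests exploit as an oracle. Genomic
inflation is summarized by the median-chi-square ratio.

Population structure is handled by the first principal component of the
centered dosage matrix, included as a fixed covariate only when it
explains at least 5% of the genotypic variance (`structure_covariate()`),
the convention for panels mixing an elite and a diverse pool. Significant
SNPs are selected by Benjamini–Hochberg at a default FDR of 30% — a
deliberately permissive level whose false positives are expected to be
filtered by multi-trait/multi-environment colocalization; 10% is the
usual display threshold and both are exposed.

Effects are reported per dosage unit; the per-environment allelic effects
used in the reaction-norm stage are homozygote contrasts (twice the
per-dosage-unit coefficient), the natural scale for inbred panels. Note
that minor-allele recoding during QC can flip the sign convention of an
effect relative to an external labeling of alleles.

## QTL delimitation

Significant markers are turned into intervals chromosome by chromosome:
pairwise LD (`r2`, squared Pearson correlation of dosage vectors) is
clustered by UPGMA on the distance `1 - r2`, the tree is cut at height
`1 - r2c`, and each cluster becomes a QTL whose boundaries are the
minimum and maximum position of its markers, with the smallest-p member
as the peak.

The critical LD `r2c` (`critical_r2()`) is the 99.9th percentile of `r2`
over 10,000 marker pairs sampled from different chromosomes — the LD
attainable by chance or panel structure. The quantile uses the type-7
linear-interpolation definition. In structured panels the unlinked-`r2`
distribution is inflated by relatedness; `corrected_r2()` removes this by
GLS-centering and whitening both dosage vectors with `V^(-1/2)`,
`V = 2K + 1e-6 I`, before correlating, and `critical_r2(corrected =
TRUE)` applies this to every sampled pair. On unstructured panels
`n * r2` for unlinked pairs is asymptotically chi-square(1), so `r2c`
is close to `qchisq(0.999, 1) / n` — a property the tests verify.

Clustering defaults to the raw `r2` distance with cutoff `1 - r2c`,
taking the stated cutoff literally; a square-root-transformed mode
(distance `1 - sqrt(r2)`, cutoff `1 - sqrt(r2c)`) is available behind
`ld_mode = "sqrt"` for workflows that normalize LD before clustering.
Neither mode is asserted as canonical. UPGMA ties are resolved by the
canonical map order of the markers, making block partitions invariant to
input order.

Two QTLs of different traits *overlap* when they share at least one
significant marker and their intervals are separated by less than one
tenth of the chromosome's physical length; platform and field QTLs
*colocalize* when their boundary intervals contain at least one common
mapped marker. Chromosome length defaults to the last mapped position (a
proxy needed for synthetic maps) and can be overridden.

## Environment integration

Earing date (DOE) confounds yield and its components: per environment,
`phenology_correct()` regresses GY, GN and TKW on DOE and keeps the
residuals (GYC, GNC, TKC), which are exactly orthogonal to DOE within
each environment. Correlation scans between platform BLUEs and field
traits control multiplicity with an effective test count: the number of
PCA axes accounting for 90% of the variance of the platform-trait matrix
times the same quantity for the genotype-by-environment matrix of the
reference field trait (`n_independent()`), with the critical correlation
`r = t / sqrt(t^2 + n - 2)` at the Bonferroni-adjusted level
(`critical_r()`).

Per-environment QTL effects are obtained by refitting the single-SNP
mixed model within each environment (`snp_effect_by_environment()`); the
alternative — extracting environment-specific effects from one
multi-environment model — was not adopted because the per-environment
refit reuses the association machinery unchanged and makes no assumption
about the G×E covariance structure. `qtl_env_regression()` then regresses
the effect on each environmental covariate (the reaction-norm
orientation; the regression `r2` is orientation-invariant, and the slope
is reported in effect units per covariate unit), Bonferroni-controlled at
`alpha / (n_SNP x n_independent_covariates)`. Registration-era trends
(`era_trends()`) are per-trait OLS of BLUE on release year with
Bonferroni control over the traits tested.

## The synthetic generator

`sim_config()` + `simulate_genotypes()` build a biallelic fully inbred
panel (dosages 0/2) by ancestral-haplotype copying: per chromosome a pool
of ancestral haplotypes carries block LD (a latent Gaussian first-order
process with correlation `exp(-d / ld_decay_bp)`, thresholded at each
marker's frequency, so marginal frequencies are exact), and each line is
a mosaic of pool haplotypes with exponential segment breakpoints of the
same mean. The pool itself must carry LD — copying from an LD-free pool
would produce no expected decay — which is why the pool is generated from
the latent process rather than independent draws. The pool size scales
with the panel (default `max(64, n_lines)`) so realized frequencies
converge to their targets. Structure is modelled as discrete
subpopulations with Balding–Nichols frequency divergence; the mixing
weights set subpopulation sizes (continuous per-line admixture is not
simulated — the discrete mixture is what inflates unlinked LD and
motivates the relatedness correction).

Platform plots add, on top of the genetic value (causal-locus effects
plus a polygenic deviate with covariance `sigma2_G K`), a random block
effect, a smooth sinusoidal surface with random phases per experiment, a
temperature-sum covariate effect, and Gaussian noise; a configurable
fraction of plots is injected as failed plants below 0.5 g. Field trials
give line i in environment e the value `mu_e + gamma_e (DOE_i - mean) +
sum_q (a_q + b_q w_e) dosage_iq / 2 + polygenic + residual`: allelic
effects are linear reaction norms in the environmental covariate `w`
(e.g. a water-stress index in [0, 1], with 0 the most stressed), and the
`gamma_e` DOE term is the phenology confounding the correction stage is
meant to remove. The recorded truth stores the per-environment effects
`a + b w` exactly. Default study conditions: 300 lines, five 600-Mb
chromosomes with 400 markers each, LD decay scale 5 Mb, three greenhouse
experiments with 8 blocks and 6 checks each, one rhizotube per non-check
genotype per experiment, and twelve field environments spanning the
stress gradient.

What the generator does *not* emulate: realistic demography or selection
footprints, epistasis and dominance (lines are fully inbred), marker
ascertainment, spatially autocorrelated residuals (the surface is smooth
and the noise white), or trait distributions with heavy tails. Passing
recovery tests on these panels shows the machinery is correct and
calibrated under its own assumptions, not that real greenhouse or trial
data meet those assumptions.

## Numerical choices and degenerate inputs

* REML optimization is a 1-D search over `log(lambda)` on [-10, 10] with
  tolerance 1e-10; eigenvalues of `K` are clipped at zero, and `K` must
  have no eigenvalue below -1e-6.
* Simulation draws from `N(0, sigma2_G K)` use a Cholesky factor of
  `K + 1e-6 I`.
* Markers constant after QC are skipped by the SNP tests with a log
  entry; constant markers are an error in LD computations (they should
  not survive QC).
* The surface basis is shrunk automatically so the total coefficient
  count stays below the plot count; below a 3 x 3 basis the surface term
  is dropped. Singular designs abort with an error naming the confounded
  terms.
* `upgma_blocks()` on a single marker returns a single block without
  clustering; a cutoff below the minimum pairwise distance yields all
  singletons.
* A null trait fitted with a random genotype effect has a small positive
  expected heritability at low replication (REML estimates of a variance
  bounded at zero have a half-normal-like sampling distribution); the
  null-H2 checks therefore use well-replicated designs, where the
  estimate concentrates near zero.
* Effect sign conventions follow the minor-allele dosage coding
  established by QC.

## Problem sizes used by the tests

Oracle-equality checks (dense GLS, loop-based kinship and LD, UPGMA merge
sequences) run on toys of 10–40 lines where brute force is exact and
instant. Calibration and recovery checks use the study-scale conditions:
500 lines and 2,000 markers for inflation, FDR and power; 10–20 seeds per
property; 200-line panels for the critical-LD null; 12 environments for
reaction norms. The acceptance script re-runs the same computations from
scratch at these sizes and writes its results as JSON.

## Known limitations

The spatial stage is a P-spline/REML approximation in the spirit of
SpATS, not a reimplementation of its SAP algorithm; effective dimensions
and heritabilities agree with the closed-form balanced cases tested but
will not numerically match SpATS output on arbitrary data. Single-locus
tests cannot separate closely linked QTLs inside one LD block. The
pipeline assumes complete, biallelic, inbred genotypes after QC;
heterozygous calls are not modelled. Interval coverage of the causal
marker depends on the panel's LD: in low-LD regions a causal marker with
no significant neighbors yields a zero-length interval at the marker
itself.
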