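#' Configuration for the synthetic study generator
#'
#' Describes a synthetic inbred-line panel and the experiments run on it:
#' the genome (chromosomes, marker density, LD decay), optional subpopulation
#' structure, causal loci with their environment reaction norms, variance
#' components per trait, the greenhouse layout of the phenotyping platform,
#' and the multi-environment field-trial network. Defaults emulate a
#' mid-sized cereal diversity panel phenotyped in a rhizotube platform and
#' evaluated in a dozen field environments.
#'
#' @param n_lines Number of inbred lines in the panel.
#' @param chromosomes Data frame with columns `chrom` (name), `length_bp`,
#'   `n_markers`.
#' @param ld_decay_bp Length scale (bp) of LD decay: ancestral-haplotype
#'   copying breakpoints are exponential with this mean, and the ancestral
#'   pool carries matching block LD.
#' @param n_anc_hap Ancestral-haplotype pool size per subpopulation. Defaults
#'   to `max(64, n_lines)` so realized allele frequencies converge to their
#'   targets as the panel grows.
#' @param structure `NULL` for an unstructured panel, or a list with
#'   `n_subpops`, `props` (mixing weights, sum to 1) and `divergence`
#'   (Balding-Nichols F between subpopulation and ancestral frequencies).
#' @param freq_range Range from which ancestral counted-allele frequencies
#'   are drawn uniformly.
#' @param target_freq Optional scalar or per-marker vector of ancestral
#'   frequencies overriding `freq_range` (used for calibration checks).
#' @param traits Named list; each element a list with `mean`, `sigma2_g`
#'   (polygenic variance) and `sigma2_e` (residual variance) in squared
#'   trait units.
#' @param qtl_spec Data frame of causal loci: `marker` (index into the map,
#'   or marker id), `trait`, `effect` (additive effect in trait units per
#'   counted-allele copy pair, applied on the platform), `a` and `b`
#'   (reaction-norm intercept/slope of the per-environment field effect
#'   against `covariate`), `covariate` (name of the environmental covariate
#'   driving the norm). `NULL` for no causal loci.
#' @param greenhouse List: `n_blocks`, `n_checks` (check genotypes replicated
#'   once per block), `n_rep` (plots per non-check genotype per experiment),
#'   `n_experiments`, optional `rows`/`cols` (grid computed to fit otherwise).
#' @param spatial_amplitude Amplitude (trait units) of the smooth 2-D
#'   greenhouse surface.
#' @param sigma2_block Block variance (squared trait units).
#' @param beta_temp Fixed-effect slope of trait on temperature sum
#'   (trait units per degree-day).
#' @param outlier_frac Fraction of plots injected as failed plants (biomass
#'   drawn below 0.5 g) in the first trait.
#' @param doe List describing heritable earing date: `mean` (Julian days),
#'   `sigma2_g`, `sigma2_e`.
#' @param environments Data frame of field environments: `env`, `mu`
#'   (environment mean of the field trait), `gamma_doe` (slope of the field
#'   trait on DOE, the phenology confounding), plus one column per
#'   environmental covariate (e.g. a water-stress index in \[0, 1\]).
#' @param field_trait Name of the simulated field trait.
#' @param field_sigma2_g,field_sigma2_e Polygenic and residual variances of
#'   the field trait.
#' @param seed Integer master seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 300,
                       chromosomes = tibble(
                         chrom = paste0("chr", 1:5),
                         length_bp = 6e8,
                         n_markers = 400L
                       ),
                       ld_decay_bp = 5e6,
                       n_anc_hap = NULL,
                       structure = NULL,
                       freq_range = c(0.1, 0.9),
                       target_freq = NULL,
                       traits = list(
                         biomass = list(mean = 2.5, sigma2_g = 0.4, sigma2_e = 0.3)
                       ),
                       qtl_spec = NULL,
                       greenhouse = list(
                         n_blocks = 8, n_checks = 6, n_rep = 1, n_experiments = 3
                       ),
                       spatial_amplitude = 0.3,
                       sigma2_block = 0.05,
                       beta_temp = 0.002,
                       outlier_frac = 0,
                       doe = list(mean = 150, sigma2_g = 16, sigma2_e = 4),
                       environments = default_environments(),
                       field_trait = "GY",
                       field_sigma2_g = 9e4,
                       field_sigma2_e = 1.6e5,
                       seed = 1L) {
  cfg <- list(
    n_lines = as.integer(n_lines),
    chromosomes = as_tibble(chromosomes),
    ld_decay_bp = ld_decay_bp,
    n_anc_hap = if (is.null(n_anc_hap)) max(64L, as.integer(n_lines)) else as.integer(n_anc_hap),
    structure = structure,
    freq_range = freq_range,
    target_freq = target_freq,
    traits = traits,
    qtl_spec = if (is.null(qtl_spec)) NULL else as_tibble(qtl_spec),
    greenhouse = modifyList(
      list(n_blocks = 8, n_checks = 6, n_rep = 1, n_experiments = 3,
           rows = NULL, cols = NULL),
      greenhouse
    ),
    spatial_amplitude = spatial_amplitude,
    sigma2_block = sigma2_block,
    beta_temp = beta_temp,
    outlier_frac = outlier_frac,
    doe = doe,
    environments = as_tibble(environments),
    field_trait = field_trait,
    field_sigma2_g = field_sigma2_g,
    field_sigma2_e = field_sigma2_e,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default synthetic field-environment network
#'
#' Twelve environments spanning the water-stress gradient, with environment
#' means and a DOE (earing date) confounding slope on yield that varies by
#' environment, plus a winter-radiation covariate.
#'
#' @return A tibble with columns `env`, `mu`, `gamma_doe`, `w_stress`,
#'   `radiation`.
#' @export
default_environments <- function() {
  n <- 12
  tibble(
    env = sprintf("E%02d", seq_len(n)),
    mu = seq(3500, 7000, length.out = n),
    gamma_doe = rep(c(-20, -5, 5, 10), length.out = n),
    w_stress = seq(0.05, 1, length.out = n),
    radiation = c(5.1, 8.7, 4.6, 9.3, 6.4, 7.8, 5.9, 8.1, 6.9, 4.9, 7.2, 9.0)
  )
}

validate_sim_config <- function(cfg) {
  ch <- cfg$chromosomes
  if (!all(c("chrom", "length_bp", "n_markers") %in% names(ch))) {
    abort("`chromosomes` needs columns chrom, length_bp, n_markers")
  }
  if (any(ch$n_markers <= 0) || any(ch$length_bp <= 0)) {
    abort("chromosome lengths and marker counts must be positive")
  }
  if (cfg$n_lines <= 1) abort("`n_lines` must exceed 1")
  if (cfg$ld_decay_bp <= 0) abort("`ld_decay_bp` must be positive")
  for (tr in names(cfg$traits)) {
    t <- cfg$traits[[tr]]
    if (t$sigma2_g < 0 || t$sigma2_e < 0) {
      abort(sprintf("variances for trait '%s' must be >= 0", tr))
    }
  }
  if (!is.null(cfg$structure)) {
    s <- cfg$structure
    if (abs(sum(s$props) - 1) > 1e-8) abort("structure `props` must sum to 1")
    if (length(s$props) != s$n_subpops) {
      abort("structure `props` must have one weight per subpopulation")
    }
    if (s$divergence < 0 || s$divergence >= 1) {
      abort("structure `divergence` must lie in [0, 1)")
    }
  }
  m_total <- sum(ch$n_markers)
  if (!is.null(cfg$qtl_spec)) {
    q <- cfg$qtl_spec
    if (is.numeric(q$marker) && any(q$marker < 1 | q$marker > m_total)) {
      abort("`qtl_spec` marker indices must index the marker map")
    }
  }
  gh <- cfg$greenhouse
  if (gh$n_blocks < 1 || gh$n_checks < 0 || gh$n_rep < 1 || gh$n_experiments < 1) {
    abort("greenhouse counts must be positive (n_checks may be 0)")
  }
  if (gh$n_checks >= cfg$n_lines) abort("more checks than lines")
  if (cfg$outlier_frac < 0 || cfg$outlier_frac > 0.5) {
    abort("`outlier_frac` must lie in [0, 0.5]")
  }
  if (!"env" %in% names(cfg$environments)) abort("`environments` needs an `env` column")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d lines, %d markers on %d chromosomes, seed %d\n",
    x$n_lines, sum(x$chromosomes$n_markers), nrow(x$chromosomes), x$seed
  ))
  if (!is.null(x$structure)) {
    cat(sprintf(
      "  structure: %d subpops (F = %.2f)\n",
      x$structure$n_subpops, x$structure$divergence
    ))
  }
  cat(sprintf(
    "  traits: %s; %d causal loci; %d environments\n",
    paste(names(x$traits), collapse = ", "),
    if (is.null(x$qtl_spec)) 0L else nrow(x$qtl_spec),
    nrow(x$environments)
  ))
  invisible(x)
}
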