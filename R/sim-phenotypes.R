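#' Simulate greenhouse platform plots (one rhizotube = one plot)
#'
#' Builds per-experiment plot tables with the structure the spatial model
#' assumes: each non-check genotype gets `n_rep` plots per experiment, check
#' genotypes are replicated once per block, and the observed value is
#'
#'   genetic value + block effect + smooth 2-D surface
#'   + beta_temp * (temperature sum - mean) + residual.
#'
#' The genetic value of line i for a trait is the trait mean, plus the
#' additive effects of configured causal loci (effect x dosage / 2), plus a
#' polygenic deviate with covariance `sigma2_g * K` (VanRaden kinship of the
#' simulated panel), plus any registration-era shift supplied via `years`.
#' A configurable fraction of plots is injected as failed plants with the
#' first trait drawn below 0.5 g.
#'
#' @param config A [sim_config()].
#' @param genotypes The panel simulated from the same config.
#' @param years Optional output of [assign_registration_years()]; its
#'   `shift_<trait>` columns are added to the genetic values.
#' @return A list with `plots` (tibble: `plot_id`, `experiment`, `genotype`,
#'   `row`, `col`, `block`, `is_check`, `tempsum`, one column per trait) and
#'   `truth` (list of class `sim_truth`: `genetic_values`, `surfaces`,
#'   `block_effects`, `outlier_plots`, `varcomp`).
#' @export
simulate_platform_plots <- function(config, genotypes, years = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "geno_matrix"))
  set.seed(config$seed + 1L)
  n <- n_lines(genotypes)
  lines <- rownames(genotypes$dosage)
  gh <- config$greenhouse
  K <- sim_kinship(genotypes)

  gvals <- genetic_values(config, genotypes, K, years)

  checks <- lines[seq_len(gh$n_checks)]
  non_checks <- setdiff(lines, checks)

  all_plots <- vector("list", gh$n_experiments)
  surfaces <- vector("list", gh$n_experiments)
  block_tabs <- vector("list", gh$n_experiments)
  for (ex in seq_len(gh$n_experiments)) {
    lay <- layout_experiment(gh, non_checks, checks)
    ph <- runif(2, 0, 2 * pi)
    surf <- config$spatial_amplitude *
      sin(2 * pi * lay$row / max(lay$row) + ph[1]) *
      cos(2 * pi * lay$col / max(lay$col) + ph[2])
    surf <- surf - mean(surf)
    b_eff <- rnorm(gh$n_blocks, 0, sqrt(config$sigma2_block))
    tempsum <- 520 + 15 * (lay$row / max(lay$row) - 0.5) +
      10 * (lay$col / max(lay$col) - 0.5) + rnorm(nrow(lay), 0, 2)
    tab <- lay
    tab$experiment <- sprintf("EXP%d", ex)
    tab$tempsum <- tempsum
    for (tr in names(config$traits)) {
      tc <- config$traits[[tr]]
      tab[[tr]] <- unname(gvals[tab$genotype, tr]) +
        b_eff[tab$block_i] + surf +
        config$beta_temp * (tempsum - mean(tempsum)) +
        rnorm(nrow(tab), 0, sqrt(tc$sigma2_e))
    }
    all_plots[[ex]] <- tab
    surfaces[[ex]] <- tibble(
      experiment = sprintf("EXP%d", ex),
      row = lay$row, col = lay$col, surface = surf
    )
    block_tabs[[ex]] <- tibble(
      experiment = sprintf("EXP%d", ex),
      block = sprintf("B%02d", seq_len(gh$n_blocks)),
      effect = b_eff
    )
  }
  plots <- dplyr::bind_rows(all_plots)
  plots$block <- sprintf("B%02d", plots$block_i)
  plots$block_i <- NULL
  plots$plot_id <- sprintf("P%05d", seq_len(nrow(plots)))

  outlier_ids <- character(0)
  n_out <- floor(config$outlier_frac * nrow(plots))
  if (n_out > 0) {
    tr1 <- names(config$traits)[1]
    idx <- sample.int(nrow(plots), n_out)
    plots[[tr1]][idx] <- runif(n_out, 0.05, 0.45)
    outlier_ids <- plots$plot_id[idx]
  }

  plots <- dplyr::relocate(
    as_tibble(plots),
    "plot_id", "experiment", "genotype", "row", "col", "block",
    "is_check", "tempsum"
  )
  truth <- structure(list(
    genetic_values = tidyr::pivot_longer(
      as_tibble(gvals, rownames = "genotype"),
      -"genotype", names_to = "trait", values_to = "value"
    ),
    surfaces = dplyr::bind_rows(surfaces),
    block_effects = dplyr::bind_rows(block_tabs),
    outlier_plots = outlier_ids,
    varcomp = config$traits
  ), class = "sim_truth")
  list(plots = plots, truth = truth)
}

# grid layout with blocks as contiguous column bands; errors when a
# user-fixed grid cannot hold all plots
layout_experiment <- function(gh, non_checks, checks) {
  plot_geno <- rep(non_checks, each = gh$n_rep)
  total <- length(plot_geno) + length(checks) * gh$n_blocks
  rows <- gh$rows %||% ceiling(sqrt(total))
  cols <- gh$cols %||% ceiling(total / rows)
  if (rows * cols < total) {
    abort(sprintf(
      "greenhouse layout (%d x %d) smaller than the %d plots required",
      rows, cols, total
    ))
  }
  cells <- tibble(
    row = rep(seq_len(rows), times = cols),
    col = rep(seq_len(cols), each = rows)
  )
  cells$block_i <- if (gh$n_blocks == 1) {
    rep(1L, nrow(cells))
  } else {
    as.integer(cut(cells$col, breaks = gh$n_blocks, labels = FALSE))
  }
  cells <- cells[seq_len(total), ]
  # deal the shuffled non-check plots across blocks after reserving check slots
  cells <- cells[order(cells$block_i, runif(nrow(cells))), ]
  geno <- character(total)
  is_check <- logical(total)
  pool <- sample(plot_geno)
  offset <- 0L
  for (b in seq_len(gh$n_blocks)) {
    slots <- which(cells$block_i == b)
    if (length(slots) < length(checks)) {
      abort("a block is too small to hold its check plots")
    }
    chk <- slots[seq_along(checks)]
    geno[chk] <- checks
    is_check[chk] <- TRUE
    rest <- setdiff(slots, chk)
    take <- min(length(rest), length(pool) - offset)
    if (take > 0) {
      geno[rest[seq_len(take)]] <- pool[offset + seq_len(take)]
      offset <- offset + take
    }
  }
  cells$genotype <- geno
  cells$is_check <- is_check
  cells[cells$genotype != "", ]
}

# polygenic + causal genetic values per line and trait (matrix lines x traits)
genetic_values <- function(config, genotypes, K, years = NULL) {
  n <- n_lines(genotypes)
  lines <- rownames(genotypes$dosage)
  out <- matrix(0, n, length(config$traits),
    dimnames = list(lines, names(config$traits))
  )
  L <- chol_psd(K)
  for (tr in names(config$traits)) {
    tc <- config$traits[[tr]]
    g <- rep(tc$mean, n)
    if (!is.null(config$qtl_spec)) {
      q <- config$qtl_spec[config$qtl_spec$trait == tr &
        !is.na(config$qtl_spec$effect), , drop = FALSE]
      if (nrow(q)) {
        for (j in seq_len(nrow(q))) {
          mk <- resolve_marker(q$marker[j], genotypes)
          g <- g + q$effect[j] * genotypes$dosage[, mk] / 2
        }
      }
    }
    if (tc$sigma2_g > 0) g <- g + sqrt(tc$sigma2_g) * drop(L %*% rnorm(n))
    if (!is.null(years)) {
      sh <- paste0("shift_", tr)
      if (sh %in% names(years)) {
        g <- g + years[[sh]][match(lines, years$genotype)]
      }
    }
    out[, tr] <- g
  }
  out
}

resolve_marker <- function(mk, genotypes) {
  if (is.numeric(mk)) genotypes$map$marker[mk] else mk
}

# lower-triangular factor of a PSD matrix with a small ridge for simulation
chol_psd <- function(K) {
  t(chol(K + diag(1e-6, nrow(K))))
}

# kinship used internally by the simulator (the analysis-side estimator
# lives in compute_kinship(); here polymorphic markers only)
sim_kinship <- function(genotypes) {
  d <- genotypes$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  v <- sweep(d[, keep, drop = FALSE], 2, 2 * p[keep])
  tcrossprod(v) / (2 * sum(p[keep] * (1 - p[keep])))
}

#' Simulate a multi-environment field-trial network
#'
#' Per environment e, the field trait of line i is
#' `mu_e + gamma_e * (DOE_i - mean DOE) + sum_q (a_q + b_q * w_e) *
#' dosage_iq / 2 + polygenic + residual`, where `w_e` is the environmental
#' covariate named in the causal-locus spec (a linear reaction norm) and the
#' `gamma_e * DOE` term is the phenology confounding that the downstream
#' correction is meant to remove. Earing date (DOE) is itself simulated as a
#' heritable genotype property.
#'
#' @param config A [sim_config()].
#' @param genotypes The panel simulated from the same config.
#' @return A list with `trial` (tibble: `genotype`, `env`, `DOE`, one column
#'   for the field trait), `covariates` (tibble: `env` + covariate columns)
#'   and `truth` (class `sim_truth`: `env_effects` with the exact
#'   per-environment causal effects `a + b * w`, `doe_genetic`,
#'   `polygenic`).
#' @export
simulate_field_trials <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "geno_matrix"))
  set.seed(config$seed + 2L)
  n <- n_lines(genotypes)
  lines <- rownames(genotypes$dosage)
  envs <- config$environments
  K <- sim_kinship(genotypes)
  L <- chol_psd(K)

  doe_g <- config$doe$mean + sqrt(config$doe$sigma2_g) * drop(L %*% rnorm(n))
  u <- if (config$field_sigma2_g > 0) {
    sqrt(config$field_sigma2_g) * drop(L %*% rnorm(n))
  } else {
    rep(0, n)
  }

  q <- config$qtl_spec
  if (!is.null(q)) q <- q[!is.na(q$a), , drop = FALSE]
  has_q <- !is.null(q) && nrow(q) > 0

  rows <- vector("list", nrow(envs))
  eff_rows <- vector("list", nrow(envs))
  for (e in seq_len(nrow(envs))) {
    doe_e <- doe_g + (e - mean(seq_len(nrow(envs)))) +
      rnorm(n, 0, sqrt(config$doe$sigma2_e))
    y <- rep(envs$mu[e], n) + envs$gamma_doe[e] * (doe_e - mean(doe_e)) + u
    if (has_q) {
      effs <- numeric(nrow(q))
      for (j in seq_len(nrow(q))) {
        w <- envs[[q$covariate[j]]][e]
        effs[j] <- q$a[j] + q$b[j] * w
        mk <- resolve_marker(q$marker[j], genotypes)
        y <- y + effs[j] * genotypes$dosage[, mk] / 2
      }
      eff_rows[[e]] <- tibble(
        marker = purrr::map_chr(q$marker, resolve_marker, genotypes = genotypes),
        env = envs$env[e],
        covariate = q$covariate,
        w = purrr::map_dbl(q$covariate, ~ envs[[.x]][e]),
        effect = effs
      )
    }
    y <- y + rnorm(n, 0, sqrt(config$field_sigma2_e))
    rows[[e]] <- tibble(
      genotype = lines, env = envs$env[e], DOE = unname(doe_e),
      value = unname(y)
    )
  }
  trial <- dplyr::bind_rows(rows)
  names(trial)[names(trial) == "value"] <- config$field_trait
  cov_cols <- setdiff(names(envs), c("mu", "gamma_doe"))
  truth <- structure(list(
    env_effects = if (has_q) dplyr::bind_rows(eff_rows) else tibble(),
    doe_genetic = tibble(genotype = lines, doe = doe_g),
    polygenic = tibble(genotype = lines, u = u)
  ), class = "sim_truth")
  list(trial = trial, covariates = envs[, cov_cols], truth = truth)
}

#' Assign cultivar registration years and era trends
#'
#' Draws a registration year per line, uniform over `year_range`, and
#' computes the additive genetic-value shift `slope * (year - mid-range)`
#' for each trait named in `trend`. Feed the result to
#' [simulate_platform_plots()] to make those shifts part of the genetic
#' values (and hence of the BLUEs a trend test sees).
#'
#' @param genotypes A [geno_matrix()].
#' @param trend Named numeric vector of slopes (trait units per year);
#'   `NULL` for no trend.
#' @param year_range Length-2 integer vector (first and last possible year).
#' @param seed Integer seed.
#' @return A tibble with `genotype`, `year`, and one `shift_<trait>` column
#'   per entry of `trend`.
#' @export
assign_registration_years <- function(genotypes, trend = NULL,
                                      year_range = c(1940, 2020),
                                      seed = 1L) {
  stopifnot(length(year_range) == 2, year_range[2] >= year_range[1])
  set.seed(seed)
  lines <- rownames(genotypes$dosage)
  yrs <- sample(seq(year_range[1], year_range[2]), length(lines), replace = TRUE)
  out <- tibble(genotype = lines, year = yrs)
  mid <- mean(year_range)
  for (tr in names(trend)) {
    out[[paste0("shift_", tr)]] <- trend[[tr]] * (yrs - mid)
  }
  out
}
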