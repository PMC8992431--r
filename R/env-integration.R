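#' Phenology correction of yield traits
#'
#' Earing date (DOE) confounds yield and its components in many
#' environments; per environment, the trait is regressed on DOE by OLS and
#' the residuals become the corrected trait (GY -> GYC, GN -> GNC,
#' TKW -> TKC). Environments without DOE keep the corrected column missing,
#' with a log entry. Within each environment the corrected values sum to
#' ~0 and are uncorrelated with DOE.
#'
#' @param trial Field-trial tibble with `genotype`, `env`, `DOE` and the
#'   trait columns.
#' @param traits Traits to correct, default the intersection of
#'   `c("GY", "GN", "TKW")` with the available columns.
#' @return `trial` with one corrected column per trait (named `GYC`,
#'   `GNC`, `TKC`, or `<trait>C`), attribute `log` (skipped environments).
#' @export
phenology_correct <- function(trial, traits = NULL) {
  trial <- as_tibble(trial)
  if (is.null(traits)) {
    traits <- intersect(c("GY", "GN", "TKW"), names(trial))
  }
  cname <- function(tr) {
    switch(tr, GY = "GYC", GN = "GNC", TKW = "TKC", paste0(tr, "C"))
  }
  log <- tibble(env = character(0), trait = character(0), reason = character(0))
  for (tr in traits) {
    out_col <- rep(NA_real_, nrow(trial))
    for (e in unique(trial$env)) {
      idx <- which(trial$env == e)
      doe <- trial$DOE[idx]
      y <- trial[[tr]][idx]
      ok <- is.finite(doe) & is.finite(y)
      if (sum(ok) < 3 || all(!is.finite(doe))) {
        log <- dplyr::bind_rows(log, tibble(
          env = e, trait = tr, reason = "DOE or trait unavailable"
        ))
        next
      }
      f <- lm(y[ok] ~ doe[ok])
      out_col[idx[ok]] <- residuals(f)
    }
    trial[[cname(tr)]] <- out_col
  }
  attr(trial, "log") <- log
  trial
}

#' Critical Pearson correlation
#'
#' Two-sided critical value of the sample correlation at level `alpha` for
#' sample size `n`: `r_crit = t / sqrt(t^2 + n - 2)` with `t` the Student
#' quantile at `1 - alpha/2` on `n - 2` degrees of freedom. E.g. 0.139 for
#' (n = 200, alpha = 0.05) and 0.073 for (n = 715, alpha = 0.05).
#'
#' @param n Sample size (>= 3).
#' @param alpha Two-sided level in (0, 1).
#' @return The critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (any(n < 3)) abort("`n` must be at least 3")
  stopifnot(all(alpha > 0 & alpha < 1))
  t <- qt(1 - alpha / 2, df = n - 2)
  t / sqrt(t^2 + n - 2)
}

#' Effective number of independent variables
#'
#' The number of principal-component axes needed to account for at least
#' `threshold` (default 90%) of the variability of the standardized
#' columns — the effective test count used in Bonferroni corrections of
#' correlation scans. Zero-variance columns are dropped with a log entry.
#'
#' @param x Data frame or matrix of numeric columns (rows with missing
#'   values are dropped listwise).
#' @param threshold Cumulative explained-variance target, default 0.90.
#' @return Integer count, attribute `dropped` (zero-variance columns).
#' @export
n_independent <- function(x, threshold = 0.90) {
  x <- as.matrix(as.data.frame(x))
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2) abort("need at least two columns")
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0]
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 1) {
    out <- 1L
    attr(out, "dropped") <- dropped
    return(out)
  }
  pc <- prcomp(x, scale. = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  out <- as.integer(which(cum >= threshold - 1e-12)[1])
  attr(out, "dropped") <- dropped
  out
}

#' Platform-by-field trait correlations with effective-test control
#'
#' Pearson correlation between each platform trait BLUE and each field
#' trait in each environment, flagged at per-test levels (0.05, 0.01) and
#' at the Bonferroni level `alpha / (n_indep_traits x n_indep_envs)`, where
#' the two counts are effective numbers of independent variables
#' ([n_independent()]) of the platform-trait matrix and of the
#' genotype-by-environment matrix of the reference field trait.
#'
#' @param blues Platform BLUEs (`genotype`, `trait`, `blue`).
#' @param trial Field trial tibble (`genotype`, `env`, trait columns).
#' @param field_traits Field trait columns to correlate.
#' @param ref_trait Field trait whose genotype x environment matrix defines
#'   the independent-environment count (default the first of
#'   `field_traits`).
#' @param alpha Base level for the Bonferroni correction, default 0.05.
#' @param min_n Cells with fewer shared genotypes are omitted (default 3).
#' @return Tibble `platform_trait`, `field_trait`, `env`, `n`, `r`,
#'   `sig_05`, `sig_01`, `sig_bonferroni`; attributes `n_indep_traits`,
#'   `n_indep_envs`, `critical_r_bonferroni`.
#' @export
trait_field_correlations <- function(blues, trial, field_traits,
                                     ref_trait = field_traits[1],
                                     alpha = 0.05, min_n = 3) {
  bw <- tidyr::pivot_wider(
    dplyr::select(blues, "genotype", "trait", "blue"),
    names_from = "trait", values_from = "blue"
  )
  p_traits <- setdiff(names(bw), "genotype")
  nit <- if (length(p_traits) >= 2) {
    as.integer(n_independent(bw[, p_traits]))
  } else {
    1L
  }
  env_mat <- tidyr::pivot_wider(
    dplyr::select(trial, "genotype", "env", dplyr::all_of(ref_trait)),
    names_from = "env", values_from = dplyr::all_of(ref_trait)
  )
  nie <- if (ncol(env_mat) >= 3) {
    as.integer(n_independent(env_mat[, -1]))
  } else {
    1L
  }
  alpha_b <- alpha / (nit * nie)

  grid <- tidyr::expand_grid(
    platform_trait = p_traits,
    field_trait = field_traits,
    env = unique(trial$env)
  )
  rows <- purrr::pmap(grid, function(platform_trait, field_trait, env) {
    tt <- trial[trial$env == env, c("genotype", field_trait)]
    m <- dplyr::inner_join(
      bw[, c("genotype", platform_trait)], tt,
      by = "genotype"
    )
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) < min_n) return(NULL)
    r <- cor(m[[platform_trait]], m[[field_trait]])
    n <- nrow(m)
    tibble(
      platform_trait = platform_trait, field_trait = field_trait, env = env,
      n = n, r = r,
      sig_05 = abs(r) > critical_r(n, 0.05),
      sig_01 = abs(r) > critical_r(n, 0.01),
      sig_bonferroni = abs(r) > critical_r(n, alpha_b)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_indep_traits") <- nit
  attr(out, "n_indep_envs") <- nie
  attr(out, "alpha_bonferroni") <- alpha_b
  out
}

#' Multi-trait R of a field trait on platform predictors
#'
#' OLS of the response on all predictors; R is the Pearson correlation
#' between fitted and observed values (non-negative). Collinear predictors
#' are handled by dropping aliased columns (least-squares on the reduced
#' basis), with a log attribute.
#'
#' @param data Data frame holding response and predictors.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return R in \[0, 1\]; attributes `r_squared`, `aliased`.
#' @export
multi_trait_R <- function(data, response, predictors) {
  d <- as.data.frame(data[, c(response, predictors)])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) <= length(predictors) + 1) {
    abort("need more observations than predictors + 1")
  }
  form <- stats::as.formula(paste(
    sprintf("`%s`", response), "~",
    paste(sprintf("`%s`", predictors), collapse = " + ")
  ))
  f <- lm(form, data = d)
  aliased <- names(which(is.na(coef(f))))
  r <- cor(f$fitted.values, d[[response]])
  out <- max(r, 0)
  attr(out, "r_squared") <- out^2
  attr(out, "aliased") <- aliased
  out
}

#' Per-environment effect of one SNP on a field trait
#'
#' For each environment, the association mixed model is refitted on that
#' environment's genotype values (EMMA null + GLS for the single marker),
#' giving the marker's allelic-effect estimate and standard error there —
#' the per-environment QTL effects whose dependence on environmental
#' covariates defines the reaction norm. Environments with fewer than
#' `min_n` genotypes are skipped and logged.
#'
#' @param trial Field trial (`genotype`, `env`, trait columns).
#' @param geno QC'd [geno_matrix()].
#' @param marker Marker id.
#' @param trait Field trait column (use a phenology-corrected column to
#'   remove DOE confounding).
#' @param kinship Optional precomputed kinship on the full panel.
#' @param min_n Minimum genotypes per environment, default 10.
#' @return Tibble `env`, `n`, `effect`, `se`, `p`; attribute `skipped`.
#'   Effects are allelic-substitution effects (contrast between the two
#'   homozygous classes, i.e. twice the per-dosage-unit coefficient).
#' @export
snp_effect_by_environment <- function(trial, geno, marker, trait,
                                      kinship = NULL, min_n = 10) {
  stopifnot(marker %in% colnames(geno$dosage))
  if (is.null(kinship)) kinship <- compute_kinship(geno)
  skipped <- character(0)
  rows <- purrr::map(unique(trial$env), function(e) {
    tt <- trial[trial$env == e, c("genotype", trait)]
    tt <- tt[stats::complete.cases(tt), ]
    keep <- intersect(rownames(geno$dosage), tt$genotype)
    if (length(keep) < min_n) {
      skipped <<- c(skipped, e)
      return(NULL)
    }
    y <- setNames(tt[[trait]][match(keep, tt$genotype)], keep)
    g <- geno_subset(geno, lines = keep, markers = marker)
    null <- fit_null_model(y, kinship[keep, keep])
    res <- test_snps(g, null)
    # allelic effect = contrast between the two homozygous classes
    # (2 x the per-dosage-unit GLS coefficient, dosages being 0/2)
    tibble(
      env = e, n = length(keep),
      effect = 2 * res$beta, se = 2 * res$se, p = res$p
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Regress per-environment QTL effects on environmental covariates
#'
#' One OLS per covariate: `effect ~ covariate` across environments (the
#' reaction-norm orientation; r2 is orientation-invariant). Significance is
#' Bonferroni-controlled at `alpha / (n_snp x n_indep_covariates)`, with
#' the effective covariate count from [n_independent()] on the covariate
#' matrix. Constant covariates are skipped with a log entry.
#'
#' @param effects Per-environment effect table
#'   ([snp_effect_by_environment()]), one marker.
#' @param covariates Environment covariate tibble (`env` + numeric
#'   columns).
#' @param alpha Base level, default 0.05.
#' @param n_snp Number of significant SNPs being examined (the multiplicity
#'   of the scan), default 1.
#' @return Tibble `covariate`, `n_env`, `slope`, `intercept`, `r_squared`,
#'   `p`, `significant`; attributes `alpha_bonferroni`,
#'   `n_indep_covariates`, `skipped`.
#' @export
qtl_env_regression <- function(effects, covariates, alpha = 0.05, n_snp = 1) {
  cov_cols <- setdiff(names(covariates), "env")
  cov_cols <- cov_cols[vapply(covariates[cov_cols], is.numeric, logical(1))]
  m <- dplyr::inner_join(effects, covariates, by = "env")
  if (nrow(m) < 3) abort("need at least 3 environments with effect and covariate")
  n_ind <- if (length(cov_cols) >= 2) {
    as.integer(n_independent(covariates[, cov_cols]))
  } else {
    1L
  }
  alpha_b <- alpha / (n_snp * n_ind)
  skipped <- character(0)
  rows <- purrr::map(cov_cols, function(cv) {
    w <- m[[cv]]
    if (sd(w) == 0) {
      skipped <<- c(skipped, cv)
      return(NULL)
    }
    if (sd(m$effect) < 1e-12) {
      # flat effects carry no reaction norm
      return(tibble(
        covariate = cv, n_env = nrow(m), slope = 0,
        intercept = mean(m$effect), r_squared = 0, p = 1, significant = FALSE
      ))
    }
    f <- lm(m$effect ~ w)
    sf <- suppressWarnings(summary(f))
    slope <- coef(f)[2]
    p <- sf$coefficients[2, 4]
    tibble(
      covariate = cv, n_env = nrow(m),
      slope = unname(slope), intercept = unname(coef(f)[1]),
      r_squared = sf$r.squared, p = p, significant = p < alpha_b
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha_bonferroni") <- alpha_b
  attr(out, "n_indep_covariates") <- n_ind
  attr(out, "skipped") <- skipped
  out
}

#' Trait trends over cultivar registration years
#'
#' Tests for past (indirect) selection: per trait, OLS of the adjusted mean
#' on the registration year, with a Bonferroni flag at
#' `0.05 / n_traits_tested`.
#'
#' @param blues Platform BLUEs (`genotype`, `trait`, `blue`).
#' @param years Tibble `genotype`, `year`.
#' @param n_traits_tested Multiplicity for the Bonferroni correction;
#'   default the number of traits in `blues`.
#' @param min_n Minimum lines with years, default 10.
#' @return Tibble `trait`, `n`, `slope`, `se`, `p`, `bonferroni_significant`.
#' @export
era_trends <- function(blues, years, n_traits_tested = NULL, min_n = 10) {
  m <- dplyr::inner_join(blues, years[, c("genotype", "year")], by = "genotype")
  if (length(unique(m$year)) < 2) abort("all registration years are equal")
  traits <- unique(m$trait)
  if (is.null(n_traits_tested)) n_traits_tested <- length(traits)
  rows <- purrr::map(traits, function(tr) {
    d <- m[m$trait == tr & is.finite(m$blue) & is.finite(m$year), ]
    if (nrow(d) < min_n) return(NULL)
    f <- summary(lm(blue ~ year, data = d))
    tibble(
      trait = tr, n = nrow(d),
      slope = f$coefficients[2, 1], se = f$coefficients[2, 2],
      p = f$coefficients[2, 4],
      bonferroni_significant = f$coefficients[2, 4] < 0.05 / n_traits_tested
    )
  })
  dplyr::bind_rows(rows)
}
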