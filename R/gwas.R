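#' Fit the polygenic null model by REML (EMMA)
#'
#' The association model is `y = X beta + u + e` with `Var(u) = K sigma2_g`
#' and `Var(e) = I sigma2_e`. Following the efficient mixed-model
#' association scheme, the variance components are estimated once, with no
#' SNP in the model: `K` is eigendecomposed, the model is rotated onto the
#' eigenbasis, and the REML profile is maximized over the single variance
#' ratio `lambda = sigma2_g / sigma2_e`. The spectral cache is returned so
#' every per-SNP test is a cheap GLS on the rotated data.
#'
#' @param y Named numeric response (one value per line of `K`).
#' @param K Kinship matrix from [compute_kinship()].
#' @param X Optional fixed-effect covariate matrix (no intercept column; an
#'   intercept is always added).
#' @param interval Search interval for `log(lambda)`.
#' @return A list of class `emma_null`: `sigma2_g`, `sigma2_e`,
#'   `h2 = sigma2_g / (sigma2_g + sigma2_e)`, `loglik` (restricted),
#'   and the cache (`U`, `d`, rotated `y`/`X`).
#' @export
fit_null_model <- function(y, K, X = NULL, interval = c(-10, 10)) {
  if (!all(is.finite(y))) abort("`y` must be finite")
  n <- length(y)
  if (n < 10) abort("need at least 10 observations")
  stopifnot(nrow(K) == n)
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    stopifnot(identical(names(y), rownames(K)))
  }
  X <- cbind(`(Intercept)` = rep(1, n), X)
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6) abort("K is not positive semi-definite")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  p <- qr(X)$rank

  reml <- function(log_lambda) {
    w <- exp(log_lambda) * d + 1
    sw <- sqrt(w)
    fit <- lm.fit(Xs / sw, ys / sw)
    rss <- sum(fit$residuals^2)
    xtx <- crossprod(Xs / sw)
    -0.5 * ((n - p) * log(rss) + sum(log(w)) +
      determinant(xtx, logarithm = TRUE)$modulus)
  }
  opt <- optimize(reml, interval = interval, maximum = TRUE, tol = 1e-10)
  lambda <- exp(opt$maximum)
  w <- lambda * d + 1
  sw <- sqrt(w)
  fit <- lm.fit(Xs / sw, ys / sw)
  sigma2_e <- sum(fit$residuals^2) / (n - p)
  structure(list(
    sigma2_g = lambda * sigma2_e,
    sigma2_e = sigma2_e,
    h2 = lambda / (lambda + 1),
    loglik = opt$objective,
    lambda = lambda,
    U = U, d = d, ys = ys, Xs = Xs, y = y, X = X, rank_x = p
  ), class = "emma_null")
}

#' @export
print.emma_null <- function(x, ...) {
  cat(sprintf(
    "<emma_null> sigma2_g = %.4g, sigma2_e = %.4g (h2 = %.3f), n = %d\n",
    x$sigma2_g, x$sigma2_e, x$h2, length(x$y)
  ))
  invisible(x)
}

#' Per-SNP mixed-model association tests
#'
#' Each marker is tested successively by GLS with the covariance
#' `K sigma2_g + I sigma2_e` fixed from the null fit: on the whitened
#' (rotated and variance-standardized) data, the SNP dosage coefficient is
#' estimated by least squares given the fixed covariates, with a Wald t-test
#' on `n - rank(X) - 1` degrees of freedom (residual scale re-estimated per
#' SNP on the whitened model, so with `K = I` the test reduces exactly to
#' OLS). Markers that are constant after QC are skipped and logged.
#'
#' @param geno A QC'd [geno_matrix()].
#' @param null An `emma_null` from [fit_null_model()] on the same lines and
#'   covariates.
#' @return A tibble (`marker`, `chrom`, `pos`, `beta`, `se`, `statistic`,
#'   `p`) with attributes `lambda_gc` (genomic inflation, median-chi-square
#'   ratio) and `skipped` (constant markers).
#' @export
test_snps <- function(geno, null) {
  stopifnot(inherits(null, "emma_null"))
  n <- length(null$ys)
  stopifnot(nrow(geno$dosage) == n)
  sw <- sqrt(null$lambda * null$d + 1)
  yw <- null$ys / sw
  Xw <- null$Xs / sw
  Gw <- crossprod(null$U, geno$dosage) / sw

  qx <- qr(Xw)
  My <- qr.resid(qx, yw)
  MG <- qr.resid(qx, Gw)
  gMg <- colSums(MG^2)
  skipped <- colnames(geno$dosage)[gMg < 1e-10]
  ok <- gMg >= 1e-10
  beta <- unname(colSums(MG * My)[ok] / gMg[ok])
  rss <- pmax(sum(My^2) - beta^2 * unname(gMg[ok]), 0)
  df <- n - null$rank_x - 1
  se <- sqrt(rss / df / unname(gMg[ok]))
  stat <- beta / se
  pval <- 2 * pt(-abs(stat), df)
  out <- tibble(
    marker = colnames(geno$dosage)[ok],
    beta = beta, se = se, statistic = stat, p = pval
  )
  out <- dplyr::left_join(out, geno$map, by = "marker") |>
    dplyr::relocate("marker", "chrom", "pos")
  chisq <- qchisq(1 - out$p, df = 1)
  attr(out, "lambda_gc") <- median(chisq) / qchisq(0.5, df = 1)
  attr(out, "skipped") <- skipped
  if (length(skipped)) {
    warn(sprintf("%d constant marker(s) skipped", length(skipped)))
  }
  out
}

#' Benjamini-Hochberg significant set
#'
#' Step-up procedure at level `q`: markers with
#' `p <= p_(k*)`, `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param p Numeric p-values in (0, 1].
#' @param q FDR level (default 0.30, the working threshold for
#'   colocalization-oriented scans; 0.10 is the usual display threshold).
#' @return Integer indices of the significant set (empty when none).
#' @export
bh_fdr <- function(p, q = 0.30) {
  if (!length(p)) return(integer(0))
  stopifnot(all(p > 0 & p <= 1))
  which(p.adjust(p, method = "BH") <= q)
}

#' Run a genome-wide association scan
#'
#' Convenience wrapper: aligns adjusted means to the panel, optionally adds
#' the structure covariate (automatically when PC1 explains at least
#' `pc_min_var` of the genotypic variance), fits the EMMA null model, tests
#' every SNP, and flags the Benjamini-Hochberg significant set.
#'
#' @param blues Tibble with columns `genotype`, `trait`, `blue` (the output
#'   of [trait_blues()]), or a tibble with `genotype` plus one column per
#'   trait.
#' @param geno A QC'd [geno_matrix()].
#' @param trait Trait name to scan.
#' @param kinship Optional precomputed kinship (from [compute_kinship()]).
#' @param structure `"auto"` (include PC1 iff its variance share passes
#'   `pc_min_var`), `"never"`, or a numeric covariate vector named by line.
#' @param pc_min_var PC1 variance-share threshold, default 0.05.
#' @param fdr_q FDR level for the significant set, default 0.30.
#' @return An object of class `gwas_scan`: list with `results` (the
#'   [test_snps()] tibble plus `fdr_significant`), `trait`, `null`
#'   (variance components), `lambda_gc`, `fdr_q`, `covariates`
#'   (description of the fixed design).
#' @export
run_gwas <- function(blues, geno, trait, kinship = NULL,
                     structure = "auto", pc_min_var = 0.05, fdr_q = 0.30) {
  y_tab <- if (all(c("trait", "blue") %in% names(blues))) {
    blues |>
      dplyr::filter(.data$trait == !!trait) |>
      dplyr::select("genotype", value = "blue")
  } else {
    dplyr::select(blues, "genotype", value = dplyr::all_of(trait))
  }
  y_tab <- dplyr::filter(y_tab, is.finite(.data$value))
  keep <- intersect(rownames(geno$dosage), y_tab$genotype)
  if (length(keep) < 10) abort("fewer than 10 genotypes shared with the panel")
  g <- geno_subset(geno, lines = keep)
  y <- setNames(y_tab$value[match(keep, y_tab$genotype)], keep)
  K <- if (is.null(kinship)) compute_kinship(g) else kinship[keep, keep]

  cov_desc <- "intercept"
  X <- NULL
  if (is.numeric(structure)) {
    X <- cbind(pc1 = structure[keep])
    cov_desc <- "intercept + PC1"
  } else if (identical(structure, "auto")) {
    pc <- structure_covariate(g, min_var_explained = pc_min_var)
    if (!is.null(pc)) {
      X <- cbind(pc1 = pc)
      cov_desc <- sprintf(
        "intercept + PC1 (%.1f%% var)", 100 * attr(pc, "var_explained")
      )
    }
  }
  null <- fit_null_model(y, K, X)
  res <- test_snps(g, null)
  res$fdr_significant <- FALSE
  res$fdr_significant[bh_fdr(res$p, q = fdr_q)] <- TRUE
  structure(list(
    results = res,
    trait = trait,
    null = list(sigma2_g = null$sigma2_g, sigma2_e = null$sigma2_e, h2 = null$h2),
    lambda_gc = attr(res, "lambda_gc"),
    fdr_q = fdr_q,
    covariates = cov_desc,
    n = length(y)
  ), class = "gwas_scan")
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf(
    "<gwas_scan> %s: %d markers, %d lines, %d significant at FDR %.0f%% (lambda = %.2f)\n",
    x$trait, nrow(x$results), x$n, sum(x$results$fdr_significant),
    100 * x$fdr_q, x$lambda_gc
  ))
  invisible(x)
}

#' @describeIn run_gwas Per-marker tidy table.
#' @param x A `gwas_scan`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gwas_scan <- function(x, ...) as_tibble(x$results)

#' @describeIn run_gwas One-row model summary (variance components,
#'   inflation, counts).
#' @exportS3Method generics::glance
glance.gwas_scan <- function(x, ...) {
  tibble(
    trait = x$trait,
    n = x$n,
    n_markers = nrow(x$results),
    sigma2_g = x$null$sigma2_g,
    sigma2_e = x$null$sigma2_e,
    h2 = x$null$h2,
    lambda_gc = x$lambda_gc,
    fdr_q = x$fdr_q,
    n_significant = sum(x$results$fdr_significant),
    covariates = x$covariates
  )
}
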