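#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of dosage vectors, the standard r2 LD
#' estimator for inbred biallelic panels.
#'
#' @param geno A QC'd [geno_matrix()].
#' @param markers Marker ids (or indices) to include; default all.
#' @return A symmetric matrix with unit diagonal, values in \[0, 1\],
#'   attribute `corrected = FALSE`.
#' @export
pairwise_r2 <- function(geno, markers = NULL) {
  d <- geno$dosage
  if (!is.null(markers)) {
    if (is.numeric(markers)) markers <- colnames(d)[markers]
    d <- d[, markers, drop = FALSE]
  }
  sds <- apply(d, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "constant marker(s) in LD computation: %s",
      paste(colnames(d)[sds == 0], collapse = ", ")
    ))
  }
  r2 <- cor(d)^2
  diag(r2) <- 1
  attr(r2, "corrected") <- FALSE
  r2
}

# GLS-centering + whitening of dosage columns by V^(-1/2):
# mu_hat = (1' V^-1 x) / (1' V^-1 1), x_tilde = V^(-1/2) (x - mu_hat)
whiten_dosages <- function(d, V) {
  eig <- eigen(V, symmetric = TRUE)
  if (min(eig$values) <= 0) abort("V must be positive definite")
  E <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
  vinv1 <- solve(V, rep(1, nrow(V)))
  mu <- drop(crossprod(vinv1, d)) / sum(vinv1)
  E %*% sweep(d, 2, mu)
}

#' Relatedness-corrected LD between two markers
#'
#' Removes the r2 inflation created by relatedness/structure (e.g. an
#' elite + diverse mixed panel): both dosage vectors are GLS-centered and
#' whitened by `V^(-1/2)`, with `V = 2 K + ridge I` the line covariance
#' implied by the kinship matrix, and the squared (uncentered) correlation
#' of the whitened vectors is returned. With `V = I` this is the plain r2.
#'
#' @param geno A QC'd [geno_matrix()].
#' @param marker_a,marker_b Marker ids or indices.
#' @param K Kinship matrix ([compute_kinship()]); ignored when `V` given.
#' @param V Optional covariance matrix used directly.
#' @param ridge Diagonal ridge added to `2 K`, default 1e-6.
#' @return r2 corrected for relatedness, in \[0, 1\].
#' @export
corrected_r2 <- function(geno, marker_a, marker_b, K = NULL, V = NULL,
                         ridge = 1e-6) {
  if (is.null(V)) {
    if (is.null(K)) K <- compute_kinship(geno)
    V <- 2 * K + diag(ridge, nrow(K))
  }
  idx <- c(marker_a, marker_b)
  if (is.character(idx)) idx <- match(idx, colnames(geno$dosage))
  xt <- whiten_dosages(geno$dosage[, idx, drop = FALSE], V)
  r2_uncentered(xt[, 1], xt[, 2])
}

r2_uncentered <- function(a, b) {
  den <- sum(a^2) * sum(b^2)
  if (den == 0) return(NA_real_)
  min(sum(a * b)^2 / den, 1)
}

#' Critical r-squared from unlinked marker pairs
#'
#' The LD level attributable to chance or panel structure: `n_pairs` marker
#' pairs are sampled uniformly with the two members on different
#' chromosomes, their (optionally relatedness-corrected) r2 computed, and
#' the `percentile` quantile returned (type-7 linear-interpolation
#' quantile).
#'
#' @param geno A QC'd [geno_matrix()] with at least two chromosomes.
#' @param n_pairs Number of inter-chromosome pairs, default 10000.
#' @param percentile Upper quantile, default 0.999.
#' @param corrected Correct each r2 for relatedness ([corrected_r2()])?
#' @param K Kinship for the correction (computed from `geno` if needed).
#' @param ridge Ridge for the whitening covariance.
#' @param seed Optional integer seed for the pair sampling.
#' @return The critical r2 (scalar), with attribute `r2` holding the
#'   sampled values.
#' @export
critical_r2 <- function(geno, n_pairs = 10000, percentile = 0.999,
                        corrected = FALSE, K = NULL, ridge = 1e-6,
                        seed = NULL) {
  chroms <- unique(geno$map$chrom)
  if (length(chroms) < 2) abort("critical r2 needs at least two chromosomes")
  if (!is.null(seed)) set.seed(seed)
  m <- n_markers(geno)
  chr_of <- geno$map$chrom
  i <- sample.int(m, n_pairs, replace = TRUE)
  j <- sample.int(m, n_pairs, replace = TRUE)
  bad <- chr_of[i] == chr_of[j]
  while (any(bad)) {
    j[bad] <- sample.int(m, sum(bad), replace = TRUE)
    bad <- chr_of[i] == chr_of[j]
  }
  d <- geno$dosage
  if (corrected) {
    if (is.null(K)) K <- compute_kinship(geno)
    V <- 2 * K + diag(ridge, nrow(K))
    z <- whiten_dosages(d, V)
  } else {
    z <- sweep(d, 2, colMeans(d))
  }
  norms <- sqrt(colSums(z^2))
  num <- colSums(z[, i, drop = FALSE] * z[, j, drop = FALSE])
  r2 <- (num / (norms[i] * norms[j]))^2
  out <- unname(quantile(r2, percentile, type = 7, names = FALSE))
  attr(out, "r2") <- r2
  out
}
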