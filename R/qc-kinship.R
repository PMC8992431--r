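#' Marker quality control
#'
#' In order: (1) missing dosages are imputed with the marker's observed
#' allele frequency (dosage `2 p_i`), which leaves the frequency unchanged;
#' (2) dosages are recoded so the counted allele is the minor one (the
#' highest-frequency allele becomes the reference); (3) exact-duplicate
#' marker columns are collapsed to the first in map order; (4) markers with
#' minor-allele count below `mac_min` are removed; (5) allele frequencies
#' are recomputed.
#'
#' @param geno A [geno_matrix()].
#' @param mac_min Minimum minor-allele count (alleles, i.e. `sum(dosage)`),
#'   default 20.
#' @return A QC'd `geno_matrix` with no missing values; attribute
#'   `qc_log` records per-marker removals.
#' @export
qc_markers <- function(geno, mac_min = 20) {
  d <- geno$dosage
  n <- nrow(d)
  p <- colMeans(d, na.rm = TRUE) / 2
  # frequency imputation on the dosage scale
  if (anyNA(d)) {
    for (j in which(colSums(is.na(d)) > 0)) {
      d[is.na(d[, j]), j] <- 2 * p[j]
    }
  }
  # minor-allele coding: flip markers whose counted allele is the major one
  flip <- p > 0.5
  d[, flip] <- 2 - d[, flip]

  log <- tibble(marker = character(0), rule = character(0))
  dup <- duplicated(asplit(d, 2))
  if (any(dup)) {
    log <- dplyr::bind_rows(log, tibble(
      marker = colnames(d)[dup], rule = "duplicate"
    ))
  }
  ac <- colSums(d)
  mac <- pmin(ac, 2 * n - ac)
  low <- !dup & mac < mac_min
  if (any(low)) {
    log <- dplyr::bind_rows(log, tibble(
      marker = colnames(d)[low], rule = sprintf("mac<%d", mac_min)
    ))
  }
  keep <- !dup & !low
  if (!any(keep)) abort("marker QC removed every marker")
  out <- geno_matrix(
    d[, keep, drop = FALSE],
    geno$map[match(colnames(d)[keep], geno$map$marker), ]
  )
  attr(out, "qc_log") <- log
  out
}

#' VanRaden genomic relationship matrix
#'
#' `K = V V' / (2 * sum(p_i (1 - p_i)))` with `V` the dosage matrix
#' column-centered by `2 p_i` and `p_i` the counted-allele frequency at
#' marker i. Symmetric and positive semi-definite by construction.
#'
#' @param geno A QC'd [geno_matrix()] (no missing dosages).
#' @return An n x n matrix with line ids as dimnames and attribute
#'   `denominator` = `2 * sum(p (1 - p))`.
#' @export
compute_kinship <- function(geno) {
  d <- geno$dosage
  if (anyNA(d)) abort("kinship needs imputed genotypes; run qc_markers() first")
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("all markers are monomorphic; kinship undefined")
  v <- sweep(d, 2, 2 * p)
  k <- tcrossprod(v) / denom
  attr(k, "denominator") <- denom
  k
}

#' Population-structure covariate from the first genotype PC
#'
#' Principal-component scores of the centered dosage matrix. The first PC is
#' returned as a fixed-effect covariate only when it explains at least
#' `min_var_explained` of the total variance (the convention used when a
#' mixed panel shows strong structure), otherwise `NULL`.
#'
#' @param geno A QC'd [geno_matrix()].
#' @param min_var_explained Minimum variance share of PC1, default 0.05.
#' @return Named numeric vector of PC1 scores (attribute `var_explained`),
#'   or `NULL`.
#' @export
structure_covariate <- function(geno, min_var_explained = 0.05) {
  v <- sweep(geno$dosage, 2, colMeans(geno$dosage))
  sv <- svd(v, nu = 1, nv = 0)
  share <- sv$d[1]^2 / sum(sv$d^2)
  if (share < min_var_explained) {
    return(NULL)
  }
  out <- setNames(sv$u[, 1] * sv$d[1], rownames(geno$dosage))
  attr(out, "var_explained") <- share
  out
}
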