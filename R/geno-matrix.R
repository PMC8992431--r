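#' Genotype container for inbred biallelic panels
#'
#' Bundles a lines x markers dosage matrix with its marker map. Dosages count
#' copies of the non-reference allele and are 0/2 for fully inbred lines
#' (`NA` allowed before QC). The map gives the physical position of every
#' marker, sorted by (chromosome, position).
#'
#' @param dosage Numeric matrix, lines in rows (rownames = line ids), markers
#'   in columns (colnames = marker ids). Values in \{0, 2\} or `NA`.
#' @param map Data frame with columns `marker`, `chrom`, `pos` (bp, 1-based),
#'   one row per column of `dosage`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosage`,
#'   `map` (tibble, sorted by chromosome then position, matching the column
#'   order of `dosage`) and `freq` (named vector of counted-allele
#'   frequencies, `mean(dosage)/2` ignoring `NA`).
#' @export
geno_matrix <- function(dosage, map) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  map <- as_tibble(map)
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  if (nrow(map) != ncol(dosage)) {
    abort("`map` must have one row per marker column of `dosage`.")
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("L", seq_len(nrow(dosage)))
  }
  map$chrom <- as.character(map$chrom)
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  dosage <- dosage[, map$marker, drop = FALSE]
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && any(bad < 0 | bad > 2)) {
    abort("dosages must lie in [0, 2]")
  }
  out <- list(
    dosage = dosage,
    map = map,
    freq = colMeans(dosage, na.rm = TRUE) / 2
  )
  class(out) <- "geno_matrix"
  out
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_chr <- length(unique(x$map$chrom))
  cat(sprintf(
    "<geno_matrix> %d lines x %d markers on %d chromosome%s\n",
    nrow(x$dosage), ncol(x$dosage), n_chr, if (n_chr > 1) "s" else ""
  ))
  if (anyNA(x$dosage)) {
    cat(sprintf("  %.2f%% missing dosages\n", 100 * mean(is.na(x$dosage))))
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

n_lines <- function(g) nrow(g$dosage)
n_markers <- function(g) ncol(g$dosage)

#' Subset a genotype container by lines and/or markers
#'
#' @param geno A [geno_matrix()].
#' @param lines,markers Character or integer index of lines / markers to keep
#'   (`NULL` keeps all).
#' @return A `geno_matrix`.
#' @export
geno_subset <- function(geno, lines = NULL, markers = NULL) {
  d <- geno$dosage
  map <- geno$map
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, map$marker)
    d <- d[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
  }
  if (!is.null(lines)) d <- d[lines, , drop = FALSE]
  geno_matrix(d, map)
}
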