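#' Read and write genotype panels
#'
#' Genotypes travel either as a CSV dosage matrix (lines x markers) with a
#' companion 3-column map file (`marker`, `chrom`, `pos`, 1-based bp), or as
#' a VCF with phased homozygous GT calls (inbred lines). The VCF reader
#' needs the `vcfR` package.
#'
#' @param geno A [geno_matrix()].
#' @param dosage_file,map_file CSV paths for the dosage matrix (first column
#'   `line`) and marker map.
#' @name geno_io
NULL

#' @rdname geno_io
#' @export
write_geno_csv <- function(geno, dosage_file, map_file) {
  d <- as_tibble(geno$dosage, rownames = "line")
  readr::write_csv(d, dosage_file)
  readr::write_csv(geno$map, map_file)
  invisible(c(dosage_file, map_file))
}

#' @rdname geno_io
#' @export
read_geno_csv <- function(dosage_file, map_file) {
  d <- readr::read_csv(dosage_file, show_col_types = FALSE)
  map <- readr::read_csv(map_file, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  geno_matrix(m, map)
}

#' @rdname geno_io
#' @param file VCF path (uncompressed).
#' @export
write_geno_vcf <- function(geno, file) {
  d <- geno$dosage
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rootqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", rownames(d)
    ), collapse = "\t")
  ), con)
  gt <- matrix("0|0", ncol(d), nrow(d))
  td <- t(d)
  gt[td == 2] <- "1|1"
  gt[is.na(td)] <- ".|."
  body <- paste(
    geno$map$chrom, geno$map$pos, geno$map$marker, "A", "T", ".", "PASS",
    ".", "GT", apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(body, con)
  invisible(file)
}

#' @rdname geno_io
#' @export
read_geno_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(z) {
      if (any(z == ".")) return(NA_real_)
      sum(z == "1")
    }, numeric(1))
  }
  d <- apply(gt, 2, alt_count)
  map <- tibble(
    marker = rownames(gt),
    chrom = vcfR::getCHROM(v),
    pos = as.integer(vcfR::getPOS(v))
  )
  geno_matrix(t(d), map)
}

#' Write adjusted means and heritabilities
#'
#' @param blues Output of [trait_blues()].
#' @param blues_file CSV path for the per-genotype adjusted means
#'   (`genotype`, `trait`, `blue`, `se`).
#' @param h2_file Optional TSV path for the per-trait generalized
#'   heritabilities (`trait`, `H2`, `ED`, `n`).
#' @export
write_trait_blues <- function(blues, blues_file, h2_file = NULL) {
  readr::write_csv(blues, blues_file)
  h2 <- attr(blues, "h2")
  if (!is.null(h2_file) && !is.null(h2)) {
    readr::write_tsv(h2, h2_file)
  }
  invisible(blues_file)
}

#' Write a GWAS scan as TSV plus a JSON model card
#'
#' @param scan A `gwas_scan` from [run_gwas()].
#' @param results_file TSV path (marker, chrom, pos, beta, se, statistic, p,
#'   fdr_significant).
#' @param model_file Optional JSON path for the model card (variance
#'   components, inflation, covariates, FDR level).
#' @export
write_gwas <- function(scan, results_file, model_file = NULL) {
  readr::write_tsv(scan$results, results_file)
  if (!is.null(model_file)) {
    jsonlite::write_json(glance(scan), model_file,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(results_file)
}

#' Write QTL tables
#'
#' @param qtls QTL tibble from [delimit_qtls()].
#' @param tsv_file TSV path (trait, source, chrom, start, end, n_markers,
#'   peak_marker, peak_p); the marker list-column is collapsed with `;`.
#' @param bed_file Optional BED path (0-based half-open conversion of the
#'   1-based inclusive intervals).
#' @export
write_qtls <- function(qtls, tsv_file, bed_file = NULL) {
  out <- qtls
  if ("markers" %in% names(out)) {
    out$markers <- purrr::map_chr(out$markers, paste, collapse = ";")
  }
  readr::write_tsv(out, tsv_file)
  if (!is.null(bed_file)) {
    bed <- tibble(
      chrom = qtls$chrom,
      start = qtls$start - 1L,
      end = qtls$end,
      name = paste(qtls$trait, qtls$peak_marker, sep = "|")
    )
    readr::write_tsv(bed, bed_file, col_names = FALSE)
  }
  invisible(tsv_file)
}

#' Write simulation ground truth as JSON
#'
#' @param truth A `sim_truth` list.
#' @param file JSON path.
#' @export
write_sim_truth <- function(truth, file) {
  jsonlite::write_json(unclass(truth), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
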