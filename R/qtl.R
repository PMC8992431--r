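#' UPGMA LD blocks
#'
#' Average-linkage agglomerative clustering of markers on the distance
#' `d = 1 - r2`, with the tree cut at `cutoff_height` (conventionally
#' `1 - critical r2`): markers whose average LD exceeds the critical level
#' end up in the same block.
#'
#' @param ld Symmetric r2 matrix (from [pairwise_r2()], optionally
#'   sqrt-transformed by the caller).
#' @param cutoff_height Tree-cut height, `1 - r2c`.
#' @return A list of character vectors (marker ids), one per block, ordered
#'   by first member.
#' @export
upgma_blocks <- function(ld, cutoff_height) {
  ids <- colnames(ld)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(ld)))
  if (ncol(ld) == 1) return(list(ids))
  # canonical order for deterministic ties
  hc <- hclust(as.dist(1 - ld), method = "average")
  grp <- cutree(hc, h = cutoff_height)
  unname(split(ids, grp))
}

#' Build QTL intervals from LD blocks of significant markers
#'
#' One QTL per block: boundaries are the minimum and maximum map position of
#' the block's (FDR-significant) markers, the peak is the member with the
#' smallest p-value. All members of a block must lie on one chromosome
#' (clustering is run per chromosome and per trait).
#'
#' @param blocks List of marker-id vectors ([upgma_blocks()]).
#' @param map Marker map tibble (`marker`, `chrom`, `pos`).
#' @param gwas Per-marker results tibble with `marker` and `p`.
#' @param trait Trait label stored on each QTL.
#' @param source Origin label (`"platform"`, or a field environment).
#' @return A tibble of class `qtl_set`: `trait`, `source`, `chrom`, `start`,
#'   `end`, `n_markers`, `peak_marker`, `peak_p`, `markers` (list-column).
#' @export
build_qtls <- function(blocks, map, gwas, trait, source = "platform") {
  rows <- purrr::map(blocks, function(mk) {
    mm <- map[match(mk, map$marker), ]
    if (anyNA(mm$marker)) abort("block contains markers absent from the map")
    if (length(unique(mm$chrom)) > 1) {
      abort("a block spans two chromosomes; cluster per chromosome")
    }
    pp <- gwas$p[match(mk, gwas$marker)]
    tibble(
      trait = trait, source = source, chrom = mm$chrom[1],
      start = min(mm$pos), end = max(mm$pos), n_markers = length(mk),
      peak_marker = mk[which.min(pp)], peak_p = min(pp),
      markers = list(mk)
    )
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$chrom, .data$start)
  class(out) <- c("qtl_set", class(out))
  out
}

#' Delimit QTLs from a GWAS scan
#'
#' The full interval-construction chain: take the FDR-significant markers,
#' and per chromosome compute their pairwise LD, cluster into blocks by
#' UPGMA cut at `1 - r2c` (or `1 - sqrt(r2c)` on the sqrt-transformed LD
#' scale), and turn each block into a QTL interval.
#'
#' @param scan A `gwas_scan` ([run_gwas()]) or its tidy results tibble with
#'   a `fdr_significant` column.
#' @param geno The QC'd [geno_matrix()] used for the scan.
#' @param r2c Critical r2 from [critical_r2()].
#' @param ld_mode `"raw"` (distance `1 - r2`, cutoff `1 - r2c`) or `"sqrt"`
#'   (distance `1 - sqrt(r2)`, cutoff `1 - sqrt(r2c)`).
#' @param trait,source Labels stored on the QTLs (trait defaults to the
#'   scan's).
#' @return A `qtl_set` tibble (possibly 0 rows).
#' @export
delimit_qtls <- function(scan, geno, r2c, ld_mode = c("raw", "sqrt"),
                         trait = NULL, source = "platform") {
  ld_mode <- match.arg(ld_mode)
  res <- if (inherits(scan, "gwas_scan")) scan$results else scan
  if (is.null(trait)) {
    trait <- if (inherits(scan, "gwas_scan")) scan$trait else "trait"
  }
  sig <- res[res$fdr_significant, , drop = FALSE]
  empty <- tibble(
    trait = character(0), source = character(0), chrom = character(0),
    start = numeric(0), end = numeric(0), n_markers = integer(0),
    peak_marker = character(0), peak_p = numeric(0), markers = list()
  )
  if (!nrow(sig)) {
    class(empty) <- c("qtl_set", class(empty))
    return(empty)
  }
  sig <- sig[order(sig$chrom, sig$pos), ]
  out <- purrr::map(unique(sig$chrom), function(cc) {
    mk <- sig$marker[sig$chrom == cc]
    if (length(mk) == 1) {
      blocks <- list(mk)
    } else {
      ld <- pairwise_r2(geno, mk)
      if (ld_mode == "sqrt") {
        blocks <- upgma_blocks(sqrt(ld), 1 - sqrt(r2c))
      } else {
        blocks <- upgma_blocks(ld, 1 - r2c)
      }
    }
    build_qtls(blocks, geno$map, res, trait = trait, source = source)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("qtl_set", class(out))
  out
}

#' QTL overlap rule
#'
#' Two QTLs of different traits overlap when they share at least one
#' significant marker and their intervals are separated by less than one
#' tenth of the chromosome's physical length (gap 0 when they intersect).
#' QTLs on different chromosomes never overlap. Symmetric in its arguments.
#'
#' @param q1,q2 One-row slices of a `qtl_set` (or lists with fields
#'   `chrom`, `start`, `end`, `markers`).
#' @param chrom_length Physical length (bp) of the shared chromosome; by
#'   convention the last mapped marker position when true lengths are
#'   unavailable.
#' @return Logical.
#' @export
qtls_overlap <- function(q1, q2, chrom_length) {
  if (chrom_length <= 0) abort("`chrom_length` must be positive")
  g <- function(q, f) {
    v <- q[[f]]
    if (is.list(v) && f == "markers") v[[1]] else v
  }
  if (g(q1, "chrom") != g(q2, "chrom")) return(FALSE)
  shared <- length(intersect(g(q1, "markers"), g(q2, "markers"))) > 0
  if (!shared) return(FALSE)
  gap <- max(0, max(g(q1, "start"), g(q2, "start")) -
    min(g(q1, "end"), g(q2, "end")))
  gap < chrom_length / 10
}

#' Colocalization of platform and field QTLs
#'
#' Two QTLs colocalize when their boundary intervals contain at least one
#' common marker of the map.
#'
#' @param platform_qtls,field_qtls `qtl_set` tibbles sharing one map.
#' @param map The marker map (`marker`, `chrom`, `pos`).
#' @return A tibble of colocalized pairs: trait/source/peak of each side,
#'   `chrom`, `n_shared` (common mapped markers).
#' @export
colocalize <- function(platform_qtls, field_qtls, map) {
  in_interval <- function(q) {
    map$marker[map$chrom == q$chrom & map$pos >= q$start & map$pos <= q$end]
  }
  rows <- list()
  for (i in seq_len(nrow(platform_qtls))) {
    qp <- platform_qtls[i, ]
    mp <- in_interval(qp)
    for (j in seq_len(nrow(field_qtls))) {
      qf <- field_qtls[j, ]
      if (qf$chrom != qp$chrom) next
      shared <- intersect(mp, in_interval(qf))
      if (length(shared)) {
        rows[[length(rows) + 1]] <- tibble(
          platform_trait = qp$trait, platform_peak = qp$peak_marker,
          field_trait = qf$trait, field_source = qf$source,
          field_peak = qf$peak_marker, chrom = qp$chrom,
          n_shared = length(shared)
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble(
      platform_trait = character(0), platform_peak = character(0),
      field_trait = character(0), field_source = character(0),
      field_peak = character(0), chrom = character(0), n_shared = integer(0)
    ))
  }
  dplyr::bind_rows(rows)
}

#' Chromosome lengths from a marker map
#'
#' Proxy for physical chromosome length: the largest mapped position per
#' chromosome. Override with a true-lengths table when available.
#'
#' @param map Marker map tibble.
#' @return Named numeric vector (bp per chromosome).
#' @export
chrom_lengths <- function(map) {
  out <- tapply(map$pos, map$chrom, max)
  setNames(as.numeric(out), names(out))
}
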