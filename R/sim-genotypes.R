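#' Simulate a biallelic inbred-line panel with block LD decay
#'
#' Genotypes are generated by an ancestral-haplotype copying model: per
#' chromosome (and per subpopulation when structure is configured) a pool of
#' ancestral haplotypes carries block LD — a latent Gaussian first-order
#' process with correlation `exp(-d / ld_decay_bp)` between markers `d` bp
#' apart, thresholded at the marker's allele frequency — and each line is a
#' mosaic of pool haplotypes whose segment breakpoints are exponential with
#' mean `ld_decay_bp`. Lines are fully inbred, so dosages are 0/2.
#'
#' Subpopulation structure (when configured) draws subpopulation allele
#' frequencies around the ancestral frequency by a Balding-Nichols Beta with
#' the configured divergence, and assigns lines to subpopulations by the
#' mixing weights.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] with attributes `subpop` (integer membership
#'   vector, present when structure is configured) and `target_freq` (the
#'   ancestral counted-allele frequencies per marker).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_lines
  ch <- config$chromosomes

  s <- config$structure
  if (is.null(s)) {
    subpop <- rep(1L, n)
    n_subpops <- 1L
    f_div <- 0
  } else {
    n_subpops <- s$n_subpops
    f_div <- s$divergence
    sizes <- diff(round(cumsum(c(0, s$props)) * n))
    sizes[n_subpops] <- n - sum(sizes[-n_subpops])
    subpop <- rep(seq_len(n_subpops), times = sizes)
  }

  maps <- vector("list", nrow(ch))
  blocks <- vector("list", nrow(ch))
  target <- vector("list", nrow(ch))
  m_done <- 0L
  for (i in seq_len(nrow(ch))) {
    m <- ch$n_markers[i]
    pos <- sort(sample.int(ch$length_bp[i], m))
    p_anc <- if (!is.null(config$target_freq)) {
      rep_len(config$target_freq, m)
    } else {
      runif(m, config$freq_range[1], config$freq_range[2])
    }
    dos <- matrix(0, n, m)
    for (sp in seq_len(n_subpops)) {
      p_sp <- bn_frequencies(p_anc, f_div)
      pool <- sim_haplotype_pool(config$n_anc_hap, pos, config$ld_decay_bp, p_sp)
      idx <- which(subpop == sp)
      dos[idx, ] <- 2 * mosaic_copy(pool, pos, config$ld_decay_bp, length(idx))
    }
    maps[[i]] <- tibble(
      marker = sprintf("%s_m%04d", ch$chrom[i], m_done + seq_len(m)),
      chrom = ch$chrom[i],
      pos = pos
    )
    blocks[[i]] <- dos
    target[[i]] <- p_anc
    m_done <- m_done + m
  }
  map <- dplyr::bind_rows(maps)
  dosage <- do.call(cbind, blocks)
  colnames(dosage) <- map$marker
  rownames(dosage) <- sprintf("L%04d", seq_len(n))
  g <- geno_matrix(dosage, map)
  attr(g, "target_freq") <- setNames(unlist(target), map$marker)
  if (!is.null(s)) attr(g, "subpop") <- subpop
  g
}

# Balding-Nichols subpopulation frequencies around ancestral p with F = div
bn_frequencies <- function(p, div) {
  if (div == 0) return(p)
  a <- p * (1 - div) / div
  b <- (1 - p) * (1 - div) / div
  pmin(pmax(rbeta(length(p), a, b), 1e-4), 1 - 1e-4)
}

# Ancestral pool: latent AR(1) Gaussian along the chromosome, thresholded so
# the marginal allele frequency at marker k is p[k].
sim_haplotype_pool <- function(n_hap, pos, ld, p) {
  m <- length(pos)
  z <- matrix(0, n_hap, m)
  z[, 1] <- rnorm(n_hap)
  if (m > 1) {
    rho <- exp(-diff(pos) / ld)
    for (k in 2:m) {
      z[, k] <- rho[k - 1] * z[, k - 1] +
        sqrt(1 - rho[k - 1]^2) * rnorm(n_hap)
    }
  }
  sweep(z, 2, qnorm(p), "<") * 1
}

# Mosaic copying: each of n lines copies pool haplotypes over segments whose
# breakpoints are exponential with mean ld bp (equivalently, an ancestor
# switch between consecutive markers d bp apart with prob 1 - exp(-d / ld)).
mosaic_copy <- function(pool, pos, ld, n) {
  n_hap <- nrow(pool)
  m <- length(pos)
  anc <- sample.int(n_hap, n, replace = TRUE)
  out <- matrix(0, n, m)
  out[, 1] <- pool[anc, 1]
  if (m > 1) {
    p_rec <- 1 - exp(-diff(pos) / ld)
    for (k in 2:m) {
      rec <- runif(n) < p_rec[k - 1]
      if (any(rec)) anc[rec] <- sample.int(n_hap, sum(rec), replace = TRUE)
      out[, k] <- pool[anc, k]
    }
  }
  out
}

#' Mean r-squared of marker pairs by physical distance bin
#'
#' Diagnostic for the simulated LD structure: squared Pearson correlation of
#' dosage vectors for all within-chromosome marker pairs, binned by distance.
#'
#' @param geno A [geno_matrix()].
#' @param breaks Distance bin breaks in bp.
#' @return A tibble with `bin` midpoint, `mean_r2` and pair count `n`.
#' @export
ld_decay_profile <- function(geno,
                             breaks = c(0, 1e6, 5e6, 2e7, 1e8, Inf)) {
  res <- purrr::map_dfr(unique(geno$map$chrom), function(cc) {
    idx <- which(geno$map$chrom == cc)
    if (length(idx) < 2) return(NULL)
    d <- geno$dosage[, idx, drop = FALSE]
    keep <- apply(d, 2, sd) > 0
    d <- d[, keep, drop = FALSE]
    pos <- geno$map$pos[idx][keep]
    r2 <- cor(d)^2
    dd <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(r2)
    tibble(dist = dd[ut], r2 = r2[ut])
  })
  res$bin <- cut(res$dist, breaks, include.lowest = TRUE)
  res <- res[!is.na(res$bin), ]
  res |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n = dplyr::n(), .groups = "drop")
}
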