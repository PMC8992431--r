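# shared fixtures, all generated in code

# small unstructured panel
tiny_config <- function(seed = 1, n_lines = 60, n_chrom = 2, n_markers = 80,
                        greenhouse = list(n_blocks = 4, n_checks = 4,
                                          n_rep = 1, n_experiments = 1),
                        ...) {
  sim_config(
    n_lines = n_lines,
    chromosomes = tibble::tibble(
      chrom = paste0("c", seq_len(n_chrom)),
      length_bp = 1e8,
      n_markers = n_markers
    ),
    greenhouse = greenhouse,
    seed = seed,
    ...
  )
}

# two diverged subpopulations (elite + diverse style panel)
structured_config <- function(seed = 1, n_lines = 120, divergence = 0.25, ...) {
  tiny_config(
    seed = seed, n_lines = n_lines,
    structure = list(n_subpops = 2, props = c(0.5, 0.5),
                     divergence = divergence),
    ...
  )
}

# hand-built geno_matrix from a dosage matrix (markers evenly spaced)
make_geno <- function(dosage, n_chrom = 1) {
  m <- ncol(dosage)
  per <- ceiling(m / n_chrom)
  map <- tibble::tibble(
    marker = paste0("m", seq_len(m)),
    chrom = paste0("c", rep(seq_len(n_chrom), each = per)[seq_len(m)]),
    pos = rep(seq_len(per) * 1e6, n_chrom)[seq_len(m)]
  )
  colnames(dosage) <- map$marker
  geno_matrix(dosage, map)
}

# random 0/2 dosage panel with all markers polymorphic
random_panel <- function(n, m, seed = 1, n_chrom = 1) {
  set.seed(seed)
  repeat {
    d <- matrix(2 * rbinom(n * m, 1, runif(m, 0.2, 0.8)[rep(seq_len(m), each = n)]),
      n, m
    )
    if (all(colMeans(d) > 0 & colMeans(d) < 2)) break
  }
  rownames(d) <- sprintf("L%03d", seq_len(n))
  make_geno(d, n_chrom = n_chrom)
}
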