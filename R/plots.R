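#' Manhattan plot of a GWAS scan
#'
#' @param scan A `gwas_scan` ([run_gwas()]) or its tidy results.
#' @param highlight_fdr Colour the FDR-significant markers?
#' @return A ggplot.
#' @export
plot_manhattan <- function(scan, highlight_fdr = TRUE) {
  res <- if (inherits(scan, "gwas_scan")) scan$results else as_tibble(scan)
  res <- dplyr::arrange(res, .data$chrom, .data$pos)
  offs <- res |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos), .groups = "drop")
  offs$offset <- cumsum(dplyr::lag(offs$len, default = 0))
  res <- dplyr::left_join(res, offs[, c("chrom", "offset")], by = "chrom")
  res$x <- res$pos + res$offset
  p <- ggplot2::ggplot(res, ggplot2::aes(.data$x, -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chrom), size = 0.6,
      show.legend = FALSE) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (highlight_fdr && "fdr_significant" %in% names(res) &&
    any(res$fdr_significant)) {
    p <- p + ggplot2::geom_point(
      data = res[res$fdr_significant, ],
      colour = "blue", size = 1.2
    )
  }
  p
}

#' @rdname plot_manhattan
#' @param object A `gwas_scan`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.gwas_scan <- function(object, ...) plot_manhattan(object)

#' QQ plot of GWAS p-values
#'
#' @param scan A `gwas_scan` or tidy results tibble.
#' @return A ggplot with the observed-vs-expected -log10(p) quantiles and
#'   the genomic-inflation estimate in the subtitle.
#' @export
plot_qq <- function(scan) {
  res <- if (inherits(scan, "gwas_scan")) scan$results else as_tibble(scan)
  lam <- if (inherits(scan, "gwas_scan")) scan$lambda_gc else NA_real_
  p <- sort(res$p)
  d <- tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(expected ~ -log[10](p)),
      y = expression(observed ~ -log[10](p)),
      subtitle = if (is.finite(lam)) sprintf("lambda = %.2f", lam) else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Fitted greenhouse spatial surface
#'
#' @param object A `spatial_fit` ([fit_spatial_model()]).
#' @param ... Unused.
#' @return A ggplot heat map of the fitted surface over (row, column).
#' @exportS3Method ggplot2::autoplot
autoplot.spatial_fit <- function(object, ...) {
  d <- tibble(
    row = object$data$row, col = object$data$col, surface = object$surface
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$surface)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "column", y = "row", fill = "surface") +
    ggplot2::theme_minimal()
}

#' Reaction-norm plot: per-environment QTL effect against a covariate
#'
#' @param effects Output of [snp_effect_by_environment()].
#' @param covariates Environment covariate tibble.
#' @param covariate Covariate column to plot against.
#' @return A ggplot with the per-environment effects (±1 SE) and the OLS
#'   line.
#' @export
plot_reaction_norm <- function(effects, covariates, covariate) {
  d <- dplyr::inner_join(effects, covariates, by = "env")
  ggplot2::ggplot(d, ggplot2::aes(.data[[covariate]], .data$effect)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$effect - .data$se, ymax = .data$effect + .data$se
      ),
      width = 0, colour = "grey60"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = covariate, y = "allelic effect") +
    ggplot2::theme_minimal()
}
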