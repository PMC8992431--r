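#' Remove outlier plots before spatial adjustment
#'
#' Two plot-level rules: (1) failed plants — plots whose root or
#' above-ground biomass is below `biomass_min` (0.5 g) are removed; (2)
#' residual outliers — after a provisional spatial fit of `trait`, plots
#' with `|standardized residual| > resid_k` are removed (a reproducible
#' stand-in for per-trait visual thresholds; default k = 4). Every removal
#' is logged with its rule.
#'
#' @param plots Plot table.
#' @param trait Trait column for the residual rule; `NULL` skips it.
#' @param biomass_min Biomass threshold in g, default 0.5.
#' @param biomass_cols Columns the biomass rule applies to (those present
#'   are used).
#' @param resid_k Standardized-residual threshold, default 4; `Inf` skips.
#' @param ... Passed to [fit_spatial_model()] for the provisional fit.
#' @return List: `plots` (filtered), `log` (tibble `plot_id`, `rule`,
#'   `value`).
#' @export
filter_outliers <- function(plots, trait = NULL, biomass_min = 0.5,
                            biomass_cols = c("biomass", "root_biomass",
                                             "shoot_biomass"),
                            resid_k = 4, ...) {
  plots <- as_tibble(plots)
  if (!"plot_id" %in% names(plots)) {
    plots$plot_id <- sprintf("P%05d", seq_len(nrow(plots)))
  }
  log <- tibble(plot_id = character(0), rule = character(0), value = numeric(0))
  for (bc in intersect(biomass_cols, names(plots))) {
    bad <- which(!is.na(plots[[bc]]) & plots[[bc]] < biomass_min)
    if (length(bad)) {
      log <- dplyr::bind_rows(log, tibble(
        plot_id = plots$plot_id[bad],
        rule = sprintf("%s<%.2g", bc, biomass_min),
        value = plots[[bc]][bad]
      ))
      plots <- plots[-bad, ]
    }
  }
  if (!nrow(plots)) abort("outlier rules removed every plot")
  if (!is.null(trait) && is.finite(resid_k)) {
    by_exp <- if ("experiment" %in% names(plots)) {
      split(plots, plots$experiment)
    } else {
      list(plots)
    }
    drop_ids <- character(0)
    for (sub in by_exp) {
      # provisional fit with genotype random: a fixed genotype effect would
      # absorb a singleton plot's own outlier into its BLUE
      fit <- fit_spatial_model(sub, trait, genotype_as = "random", ...)
      r <- fit$residuals
      z <- r / max(sd(r), 1e-12)
      bad <- which(abs(z) > resid_k)
      if (length(bad)) {
        drop_ids <- c(drop_ids, fit$data$plot_id[bad])
        log <- dplyr::bind_rows(log, tibble(
          plot_id = fit$data$plot_id[bad],
          rule = sprintf("|std resid|>%g", resid_k),
          value = z[bad]
        ))
      }
    }
    if (length(drop_ids)) plots <- plots[!plots$plot_id %in% drop_ids, ]
    if (!nrow(plots)) abort("outlier rules removed every plot")
  }
  list(plots = plots, log = log)
}

#' Remove genotypes whose adjusted means fall outside trait bounds
#'
#' Genotype-level screen applied to BLUEs: genotypes whose adjusted mean
#' exceeds a per-trait upper bound are dropped for that trait (e.g. convex
#' hull > 40,000, depth > 400, width > 200 mm, CGY > 155 mm).
#'
#' @param blues Tibble `genotype`, `trait`, `blue` ([trait_blues()]).
#' @param bounds Named list of upper bounds per trait.
#' @return List: `blues` (filtered), `log` (tibble `genotype`, `trait`,
#'   `rule`, `value`).
#' @export
filter_genotype_bounds <- function(blues,
                                   bounds = list(
                                     convex_hull = 40000, depth = 400,
                                     width = 200, cgy = 155
                                   )) {
  log <- tibble(
    genotype = character(0), trait = character(0),
    rule = character(0), value = numeric(0)
  )
  for (tr in intersect(names(bounds), unique(blues$trait))) {
    bad <- which(blues$trait == tr & blues$blue > bounds[[tr]])
    if (length(bad)) {
      log <- dplyr::bind_rows(log, tibble(
        genotype = blues$genotype[bad], trait = tr,
        rule = sprintf("blue>%g", bounds[[tr]]),
        value = blues$blue[bad]
      ))
      blues <- blues[-bad, ]
    }
  }
  list(blues = blues, log = log)
}
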