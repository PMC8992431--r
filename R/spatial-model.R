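#' Fit the spatial adjustment model for one platform trait
#'
#' Linear mixed model for plot-level platform data:
#' trait ~ intercept + genotype + beta * temperature-sum + block (random) +
#' smooth 2-D surface over (row, column). The surface is a tensor-product
#' penalized B-spline (default 8 x 8 basis) and the block and (optionally)
#' genotype effects are ridge-penalized random effects; all smoothing and
#' variance parameters are estimated by REML (via mgcv). Genotype is fitted
#' fixed to extract BLUEs and random to estimate generalized heritability.
#'
#' @param plots Plot table (one experiment): columns `genotype`, `row`,
#'   `col`, optionally `block` and `tempsum`, plus the trait column.
#' @param trait Name of the trait column.
#' @param genotype_as `"fixed"` (BLUEs) or `"random"` (heritability).
#' @param basis_dim Marginal basis dimensions of the surface, default
#'   `c(8, 8)` (reduced automatically on small grids).
#' @return An object of class `spatial_fit`: the mgcv fit plus `blues`
#'   (tibble `genotype`, `blue`, `se`; fixed mode), `ed` (effective
#'   dimension per model component), `varcomp` (block and residual
#'   variances), `surface` (per-plot fitted surface values), `residuals`.
#' @export
fit_spatial_model <- function(plots, trait,
                              genotype_as = c("fixed", "random"),
                              basis_dim = c(8, 8)) {
  genotype_as <- match.arg(genotype_as)
  plots <- as_tibble(plots)
  stopifnot(all(c("genotype", "row", "col") %in% names(plots)))
  if (!trait %in% names(plots)) {
    abort(sprintf("trait column '%s' not found", trait))
  }
  plots <- plots[is.finite(plots[[trait]]), ]
  plots$genotype <- factor(plots$genotype)
  if (nlevels(plots$genotype) < 2) abort("need at least two genotypes")
  if ("experiment" %in% names(plots) && length(unique(plots$experiment)) > 1) {
    abort("fit one experiment at a time (multiple `experiment` values found)")
  }

  plots$.y <- plots[[trait]]
  terms <- character(0)
  if (genotype_as == "fixed") {
    terms <- c(terms, "genotype")
  } else {
    terms <- c(terms, "s(genotype, bs = 're')")
  }
  has_temp <- "tempsum" %in% names(plots) && sd(plots$tempsum) > 0
  if (has_temp) {
    plots$.temp <- plots$tempsum - mean(plots$tempsum)
    terms <- c(terms, ".temp")
  }
  has_block <- "block" %in% names(plots) &&
    length(unique(plots$block)) > 1
  if (has_block) {
    plots$block <- factor(plots$block)
    terms <- c(terms, "s(block, bs = 're')")
  }
  kr <- min(basis_dim[1], length(unique(plots$row)))
  kc <- min(basis_dim[2], length(unique(plots$col)))
  # keep the total coefficient count below the number of plots
  n_fixed <- if (genotype_as == "fixed") nlevels(plots$genotype) else 1L
  budget <- nrow(plots) - n_fixed - has_temp -
    (if (has_block) length(unique(plots$block)) else 0L) - 2L
  while (kr * kc > max(budget, 0) && (kr > 3 || kc > 3)) {
    if (kr >= kc) kr <- kr - 1L else kc <- kc - 1L
  }
  has_surface <- kr >= 3 && kc >= 3 && kr * kc <= budget
  if (has_surface) {
    terms <- c(terms, sprintf("te(row, col, bs = 'ps', k = c(%d, %d))", kr, kc))
  }
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(mgcv::gam(form, data = plots, method = "REML")),
    error = function(e) {
      abort(sprintf(
        "spatial model is singular (genotype, block and surface terms confounded): %s",
        conditionMessage(e)
      ))
    }
  )

  smooth_labels <- vapply(fit$smooth, function(s) s$label, character(1))
  ed <- vapply(fit$smooth, function(s) {
    sum(fit$edf[s$first.para:s$last.para])
  }, numeric(1))
  names(ed) <- smooth_labels

  varcomp <- list(residual = fit$sig2)
  if (has_block || genotype_as == "random") {
    vc <- tryCatch(
      {
        tmp <- NULL
        utils::capture.output(
          tmp <- suppressWarnings(mgcv::gam.vcomp(fit, rescale = TRUE))
        )
        tmp
      },
      error = function(e) NULL
    )
    if (!is.null(vc) && is.matrix(vc)) {
      if (has_block && "s(block)" %in% rownames(vc)) {
        varcomp$block <- vc["s(block)", "std.dev"]^2
      }
      if (genotype_as == "random" && "s(genotype)" %in% rownames(vc)) {
        varcomp$genotype <- vc["s(genotype)", "std.dev"]^2
      }
    }
  }

  surface <- if (has_surface) {
    lbl <- grep("^te\\(row,col\\)", smooth_labels, value = TRUE)
    drop(predict(fit, type = "terms", terms = lbl))
  } else {
    rep(0, nrow(plots))
  }

  blues <- NULL
  if (genotype_as == "fixed") {
    levs <- levels(plots$genotype)
    nd <- tibble(
      genotype = factor(levs, levels = levs),
      .temp = 0,
      block = plots$block[1] %||% NA,
      row = plots$row[1], col = plots$col[1]
    )
    pr <- predict(fit,
      newdata = nd, se.fit = TRUE,
      exclude = smooth_labels, newdata.guaranteed = TRUE
    )
    blues <- tibble(
      genotype = levs, blue = as.numeric(pr$fit), se = as.numeric(pr$se.fit)
    )
  }

  structure(list(
    gam = fit, trait = trait, genotype_as = genotype_as,
    blues = blues, ed = ed, varcomp = varcomp,
    surface = as.numeric(surface), residuals = as.numeric(residuals(fit)),
    n_genotypes = nlevels(plots$genotype), data = plots
  ), class = "spatial_fit")
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat(sprintf(
    "<spatial_fit> %s (genotype %s), %d plots, %d genotypes, residual var %.4g\n",
    x$trait, x$genotype_as, nrow(x$data), x$n_genotypes, x$varcomp$residual
  ))
  invisible(x)
}

#' @describeIn fit_spatial_model Per-genotype BLUEs (fixed mode) or
#'   predicted genotype effects (random mode).
#' @param x A `spatial_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.spatial_fit <- function(x, ...) {
  if (!is.null(x$blues)) {
    return(x$blues)
  }
  # random mode: BLUPs of the genotype effect
  levs <- levels(x$data$genotype)
  sm <- which(vapply(x$gam$smooth, function(s) s$label, character(1)) == "s(genotype)")
  idx <- x$gam$smooth[[sm]]$first.para:x$gam$smooth[[sm]]$last.para
  tibble(genotype = levs, effect = unname(coef(x$gam)[idx]))
}

#' @describeIn fit_spatial_model One-row summary: variances, effective
#'   dimensions, heritability (random mode).
#' @exportS3Method generics::glance
glance.spatial_fit <- function(x, ...) {
  tibble(
    trait = x$trait,
    genotype_as = x$genotype_as,
    n_plots = nrow(x$data),
    n_genotypes = x$n_genotypes,
    sigma2_residual = x$varcomp$residual,
    sigma2_block = x$varcomp$block %||% NA_real_,
    ed_surface = sum(x$ed[grepl("^te", names(x$ed))]) %||% NA_real_,
    h2 = if (x$genotype_as == "random") generalized_heritability(x) else NA_real_
  )
}

#' Generalized heritability of a random-genotype spatial fit
#'
#' `H2 = ED_genotype / (n_genotypes - 1)`, where `ED_genotype` is the
#' effective dimension (sum of the effective degrees of freedom) of the
#' random genotype component; clipped to \[0, 1\].
#'
#' @param fit A `spatial_fit` with `genotype_as = "random"`.
#' @return H2 in \[0, 1\], attribute `ed`.
#' @export
generalized_heritability <- function(fit) {
  stopifnot(inherits(fit, "spatial_fit"))
  if (fit$genotype_as != "random") {
    abort("heritability needs the genotype fitted as random")
  }
  ed <- unname(fit$ed["s(genotype)"])
  h2 <- min(max(ed / (fit$n_genotypes - 1), 0), 1)
  attr(h2, "ed") <- ed
  h2
}

#' Adjusted genotype means across experiments
#'
#' Fits the spatial model per experiment and trait, extracts BLUEs
#' (genotype fixed) and the generalized heritability (genotype random), and
#' combines experiments by precision weighting (weights `1 / se^2`);
#' heritabilities are averaged across experiments.
#'
#' @param plots Plot table with an `experiment` column.
#' @param traits Trait columns to adjust; defaults to every numeric column
#'   that is not a design variable.
#' @param compute_h2 Also fit the random-genotype model per experiment?
#' @param ... Passed to [fit_spatial_model()].
#' @return Tibble `genotype`, `trait`, `blue`, `se`, `n_experiments`, with
#'   attribute `h2`: tibble `trait`, `H2`, `ED`, `n`.
#' @export
trait_blues <- function(plots, traits = NULL, compute_h2 = TRUE, ...) {
  plots <- as_tibble(plots)
  if (!"experiment" %in% names(plots)) plots$experiment <- "EXP1"
  design <- c(
    "plot_id", "experiment", "genotype", "row", "col", "block",
    "is_check", "tempsum"
  )
  if (is.null(traits)) {
    traits <- setdiff(names(plots)[vapply(plots, is.numeric, logical(1))],
      design
    )
  }
  blues <- list()
  h2s <- list()
  for (tr in traits) {
    per_exp <- purrr::map(unique(plots$experiment), function(ex) {
      sub <- plots[plots$experiment == ex, ]
      f <- fit_spatial_model(sub, tr, genotype_as = "fixed", ...)
      b <- f$blues
      b$experiment <- ex
      h2 <- NA_real_
      ed <- NA_real_
      if (compute_h2) {
        fr <- fit_spatial_model(sub, tr, genotype_as = "random", ...)
        h2 <- generalized_heritability(fr)
        ed <- attr(h2, "ed")
      }
      list(blues = b, h2 = as.numeric(h2), ed = ed, n = f$n_genotypes)
    })
    bb <- dplyr::bind_rows(purrr::map(per_exp, "blues"))
    comb <- bb |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(
        blue = sum(.data$blue / .data$se^2) / sum(1 / .data$se^2),
        se = sqrt(1 / sum(1 / .data$se^2)),
        n_experiments = dplyr::n(),
        .groups = "drop"
      )
    comb$trait <- tr
    blues[[tr]] <- comb
    h2s[[tr]] <- tibble(
      trait = tr,
      H2 = mean(purrr::map_dbl(per_exp, "h2")),
      ED = mean(purrr::map_dbl(per_exp, "ed")),
      n = max(purrr::map_int(per_exp, ~ as.integer(.x$n)))
    )
  }
  out <- dplyr::bind_rows(blues) |>
    dplyr::select("genotype", "trait", "blue", "se", "n_experiments")
  attr(out, "h2") <- dplyr::bind_rows(h2s)
  out
}
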