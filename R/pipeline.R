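#' Build and validate a pipeline run configuration
#'
#' A run configuration drives [run_pipeline()]: either synthetic mode
#' (a [sim_config()] under `sim`) or file mode (paths to genotype, plot,
#' trial and covariate tables), the stages to execute, the analysis
#' thresholds, the output directory and the master seed. Per-stage seeds
#' are derived deterministically from the master seed so stages can be
#' rerun in isolation.
#'
#' @param sim Optional [sim_config()] (synthetic mode).
#' @param files Optional named list of input paths: `dosage`, `map` (or
#'   `vcf`), `plots`, `trial`, `covariates`.
#' @param stages Character subset of
#'   `c("simulate", "adjust", "gwas", "qtl", "integrate")`.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param mac_min,fdr_q,pc_min_var,r2c_percentile,r2c_pairs,ld_mode,alpha
#'   Analysis thresholds (see the stage functions).
#' @param traits Platform traits to adjust and scan; default all.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(sim = NULL, files = NULL,
                       stages = c("simulate", "adjust", "gwas", "qtl",
                                  "integrate"),
                       out_dir = tempfile("rootqtl_run_"),
                       seed = 1L,
                       mac_min = 20, fdr_q = 0.30, pc_min_var = 0.05,
                       r2c_percentile = 0.999, r2c_pairs = 10000,
                       ld_mode = "raw", alpha = 0.05, traits = NULL) {
  stages <- match.arg(
    stages,
    c("simulate", "adjust", "gwas", "qtl", "integrate"),
    several.ok = TRUE
  )
  if (is.null(sim) && is.null(files)) {
    abort("provide either `sim` (synthetic mode) or `files`")
  }
  if (!is.null(files)) {
    for (f in unlist(files)) {
      if (!file.exists(f)) abort(sprintf("input file not found: %s", f))
    }
  }
  stopifnot(
    mac_min >= 0, fdr_q > 0, fdr_q <= 1, pc_min_var >= 0, pc_min_var <= 1,
    r2c_percentile > 0, r2c_percentile < 1, r2c_pairs > 0,
    ld_mode %in% c("raw", "sqrt"), alpha > 0, alpha < 1
  )
  structure(list(
    sim = sim, files = files, stages = stages, out_dir = out_dir,
    seed = as.integer(seed), mac_min = mac_min, fdr_q = fdr_q,
    pc_min_var = pc_min_var, r2c_percentile = r2c_percentile,
    r2c_pairs = r2c_pairs, ld_mode = ld_mode, alpha = alpha,
    traits = traits
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [run_config()] fields; a `sim` block (fields of
#' [sim_config()]) selects synthetic mode. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c(
    "sim", "files", "stages", "out_dir", "seed", "mac_min", "fdr_q",
    "pc_min_var", "r2c_percentile", "r2c_pairs", "ld_mode", "alpha", "traits"
  )
  extra <- setdiff(names(y), known)
  if (length(extra)) {
    abort(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  }
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    if (!is.null(sim_args$chromosomes)) {
      sim_args$chromosomes <- dplyr::bind_rows(sim_args$chromosomes)
    }
    if (!is.null(sim_args$environments)) {
      sim_args$environments <- dplyr::bind_rows(sim_args$environments)
    }
    if (!is.null(sim_args$qtl_spec)) {
      sim_args$qtl_spec <- dplyr::bind_rows(sim_args$qtl_spec)
    }
    y$sim <- do.call(sim_config, sim_args)
  }
  do.call(run_config, y)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order: simulate (or load) ->
#' spatial adjustment -> GWAS -> QTL delimitation -> environment
#' integration. Every output table is written under the configured output
#' directory together with a provenance JSON (config hash, master seed,
#' thresholds used). Identical config + seed produce byte-identical
#' outputs.
#'
#' @param config A [run_config()] (or a YAML path).
#' @return The run manifest: a list with `out_dir`, `config_hash`, `seed`,
#'   `stages`, `files` (tibble stage/file), and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    out_dir = config$out_dir,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    stages = config$stages,
    files = tibble(stage = character(0), file = character(0))
  )
  add_file <- function(stage, path) {
    manifest$files <<- dplyr::bind_rows(
      manifest$files, tibble(stage = stage, file = basename(path))
    )
  }
  results <- list()

  # ---- inputs: simulate or load ------------------------------------------
  if ("simulate" %in% config$stages) {
    sim <- config$sim %||% sim_config(seed = config$seed)
    sim$seed <- config$seed
    geno <- simulate_genotypes(sim)
    plat <- simulate_platform_plots(sim, geno)
    field <- simulate_field_trials(sim, geno)
    results$geno <- geno
    results$plots <- plat$plots
    results$trial <- field$trial
    results$covariates <- field$covariates
    results$truth <- list(platform = plat$truth, field = field$truth)
    write_geno_csv(
      geno,
      file.path(config$out_dir, "genotypes.csv"),
      file.path(config$out_dir, "marker_map.csv")
    )
    readr::write_csv(plat$plots, file.path(config$out_dir, "plots.csv"))
    readr::write_csv(field$trial, file.path(config$out_dir, "trial.csv"))
    readr::write_csv(
      field$covariates, file.path(config$out_dir, "env_covariates.csv")
    )
    write_sim_truth(
      plat$truth, file.path(config$out_dir, "truth_platform.json")
    )
    for (f in c(
      "genotypes.csv", "marker_map.csv", "plots.csv", "trial.csv",
      "env_covariates.csv", "truth_platform.json"
    )) {
      add_file("simulate", f)
    }
  } else if (!is.null(config$files)) {
    fl <- config$files
    results$geno <- if (!is.null(fl$vcf)) {
      read_geno_vcf(fl$vcf)
    } else {
      read_geno_csv(fl$dosage, fl$map)
    }
    if (!is.null(fl$plots)) {
      results$plots <- readr::read_csv(fl$plots, show_col_types = FALSE)
    }
    if (!is.null(fl$trial)) {
      results$trial <- readr::read_csv(fl$trial, show_col_types = FALSE)
    }
    if (!is.null(fl$covariates)) {
      results$covariates <- readr::read_csv(fl$covariates, show_col_types = FALSE)
    }
  }

  # ---- spatial adjustment ------------------------------------------------
  if ("adjust" %in% config$stages) {
    if (is.null(results$plots)) abort("adjust stage needs a plot table")
    filt <- filter_outliers(results$plots, trait = NULL)
    blues <- trait_blues(filt$plots, traits = config$traits)
    results$blues <- blues
    write_trait_blues(
      blues,
      file.path(config$out_dir, "trait_blues.csv"),
      file.path(config$out_dir, "heritability.tsv")
    )
    readr::write_tsv(filt$log, file.path(config$out_dir, "removals.tsv"))
    for (f in c("trait_blues.csv", "heritability.tsv", "removals.tsv")) {
      add_file("adjust", f)
    }
  }

  # ---- association -------------------------------------------------------
  if ("gwas" %in% config$stages) {
    if (is.null(results$blues)) {
      abort("gwas stage needs adjusted means (run the adjust stage)")
    }
    geno_qc <- qc_markers(results$geno, mac_min = config$mac_min)
    results$geno_qc <- geno_qc
    results$kinship <- compute_kinship(geno_qc)
    traits <- unique(results$blues$trait)
    results$scans <- purrr::map(setNames(traits, traits), function(tr) {
      sc <- run_gwas(results$blues, geno_qc, tr,
        kinship = results$kinship,
        pc_min_var = config$pc_min_var, fdr_q = config$fdr_q
      )
      write_gwas(
        sc,
        file.path(config$out_dir, sprintf("gwas_%s.tsv", tr)),
        file.path(config$out_dir, sprintf("gwas_%s_model.json", tr))
      )
      add_file("gwas", sprintf("gwas_%s.tsv", tr))
      sc
    })
  }

  # ---- qtl delimitation --------------------------------------------------
  if ("qtl" %in% config$stages) {
    if (is.null(results$scans)) {
      abort("qtl stage needs GWAS results (run the gwas stage)")
    }
    set.seed(config$seed + 101L)
    results$r2c <- as.numeric(critical_r2(
      results$geno_qc,
      n_pairs = config$r2c_pairs, percentile = config$r2c_percentile
    ))
    results$qtls <- dplyr::bind_rows(purrr::map(
      results$scans,
      ~ delimit_qtls(.x, results$geno_qc, results$r2c, ld_mode = config$ld_mode)
    ))
    write_qtls(
      results$qtls,
      file.path(config$out_dir, "qtls.tsv"),
      file.path(config$out_dir, "qtls.bed")
    )
    add_file("qtl", "qtls.tsv")
    add_file("qtl", "qtls.bed")
  }

  # ---- environment integration -------------------------------------------
  if ("integrate" %in% config$stages) {
    if (is.null(results$trial)) abort("integrate stage needs a trial table")
    if (is.null(results$blues)) abort("integrate stage needs adjusted means")
    trial <- phenology_correct(results$trial)
    results$trial_corrected <- trial
    field_traits <- intersect(
      c("GYC", "GY", "GNC", "GN", "TKC", "TKW"), names(trial)
    )
    results$correlations <- trait_field_correlations(
      results$blues, trial,
      field_traits = field_traits, alpha = config$alpha
    )
    readr::write_tsv(
      results$correlations, file.path(config$out_dir, "correlations.tsv")
    )
    add_file("integrate", "correlations.tsv")
    if (!is.null(results$qtls) && nrow(results$qtls) &&
      !is.null(results$covariates)) {
      target <- if ("GYC" %in% names(trial)) "GYC" else field_traits[1]
      peaks <- unique(results$qtls$peak_marker)
      regs <- purrr::map(peaks, function(mk) {
        eff <- snp_effect_by_environment(
          trial, results$geno_qc, mk, target,
          kinship = results$kinship
        )
        if (nrow(eff) < 3) return(NULL)
        rr <- qtl_env_regression(eff, results$covariates,
          alpha = config$alpha, n_snp = length(peaks)
        )
        rr$marker <- mk
        rr
      })
      results$env_regressions <- dplyr::bind_rows(regs)
      if (!is.null(results$env_regressions) && nrow(results$env_regressions)) {
        readr::write_tsv(
          results$env_regressions,
          file.path(config$out_dir, "qtl_env_regressions.tsv")
        )
        add_file("integrate", "qtl_env_regressions.tsv")
      }
    }
  }

  provenance <- list(
    config_hash = manifest$config_hash,
    seed = config$seed,
    stages = config$stages,
    thresholds = config[c(
      "mac_min", "fdr_q", "pc_min_var", "r2c_percentile", "r2c_pairs",
      "ld_mode", "alpha"
    )]
  )
  jsonlite::write_json(
    provenance, file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  add_file("provenance", "provenance.json")
  manifest$results <- results
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "<run_manifest> seed %d, hash %s\n  stages: %s\n  %d files in %s\n",
    x$seed, x$config_hash, paste(x$stages, collapse = " -> "),
    nrow(x$files), x$out_dir
  ))
  invisible(x)
}
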