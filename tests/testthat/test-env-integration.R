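test_that("phenology correction is per-environment OLS residuals", {
  # 6-row toy vs hand-computed residuals
  trial <- tibble::tibble(
    genotype = paste0("g", 1:6), env = "E1",
    DOE = c(140, 145, 150, 155, 160, 165),
    GY = c(5000, 4900, 4700, 4600, 4300, 4200)
  )
  out <- phenology_correct(trial)
  f <- lm(GY ~ DOE, data = trial)
  expect_equal(out$GYC, unname(residuals(f)), tolerance = 1e-12)
  # orthogonality and centering within environment
  expect_lt(abs(cor(out$GYC, out$DOE)), 1e-10)
  expect_lt(abs(sum(out$GYC)), 1e-9)

  # trait exactly linear in DOE: corrected identically 0
  trial2 <- trial
  trial2$GY <- 100 - 3 * trial2$DOE
  out2 <- phenology_correct(trial2)
  expect_lt(max(abs(out2$GYC)), 1e-9)

  # constant DOE: corrected = trait - environment mean
  trial3 <- trial
  trial3$DOE <- 150
  out3 <- phenology_correct(trial3)
  expect_equal(out3$GYC, trial3$GY - mean(trial3$GY), tolerance = 1e-9)

  # missing DOE: column absent for that environment, logged
  trial4 <- dplyr::bind_rows(trial, tibble::tibble(
    genotype = paste0("g", 1:4), env = "E2", DOE = NA_real_,
    GY = c(1, 2, 3, 4)
  ))
  out4 <- phenology_correct(trial4)
  expect_true(all(is.na(out4$GYC[out4$env == "E2"])))
  expect_equal(attr(out4, "log")$env, "E2")
})

test_that("critical r reproduces its closed form and published reference values", {
  expect_equal(round(critical_r(200, 0.05), 3), 0.139)
  expect_equal(round(critical_r(200, 0.01), 3), 0.182)
  expect_equal(round(critical_r(715, 0.05), 3), 0.073)
  expect_equal(round(critical_r(715, 0.01), 3), 0.096)
  # limits and monotonicity
  expect_lt(critical_r(200, 0.999), 0.001)
  ns <- c(10, 50, 200, 1000)
  expect_true(all(diff(critical_r(ns, 0.05)) < 0))
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  expect_true(all(diff(vapply(alphas, critical_r, numeric(1), n = 100)) < 0))
  expect_error(critical_r(2, 0.05), "at least 3")
})

test_that("effective number of independent variables follows the PCA rule", {
  # 10 mutually orthogonal standardized columns -> 9 axes reach 90%
  set.seed(1)
  x <- qr.Q(qr(matrix(rnorm(400), 40, 10)))
  expect_equal(as.integer(n_independent(x)), 9L)
  # all columns identical -> 1
  y <- matrix(rep(rnorm(30), 4), 30, 4)
  expect_equal(as.integer(n_independent(y)), 1L)
  # block-structured covariance vs direct eigen cumulative sum
  set.seed(2)
  b1 <- rnorm(50)
  b2 <- rnorm(50)
  z <- cbind(
    b1 + rnorm(50, 0, 0.1), b1 + rnorm(50, 0, 0.1),
    b2 + rnorm(50, 0, 0.1), b2 + rnorm(50, 0, 0.1), rnorm(50)
  )
  ev <- eigen(cor(z), symmetric = TRUE, only.values = TRUE)$values
  want <- which(cumsum(ev) / sum(ev) >= 0.90)[1]
  expect_equal(as.integer(n_independent(z)), as.integer(want))
  # zero-variance columns dropped with a log
  z2 <- cbind(z, 0)
  out <- n_independent(z2)
  expect_length(attr(out, "dropped"), 1)
})

test_that("platform-field correlation scan flags exact and null cases correctly", {
  set.seed(3)
  n <- 60
  genos <- sprintf("g%03d", 1:n)
  depth <- rnorm(n)
  blues <- tibble::tibble(
    genotype = rep(genos, 2),
    trait = rep(c("depth", "width"), each = n),
    blue = c(depth, rnorm(n))
  )
  # field trait copied from the platform trait: r = 1 everywhere
  trial <- tibble::tibble(
    genotype = genos, env = "E1", GY = depth, DOE = rnorm(n)
  )
  ct <- trait_field_correlations(blues, trial, field_traits = "GY")
  row <- ct[ct$platform_trait == "depth", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_true(row$sig_05 && row$sig_01 && row$sig_bonferroni)

  # closed-form oracle on one cell
  row_w <- ct[ct$platform_trait == "width", ]
  x <- blues$blue[blues$trait == "width"]
  expect_equal(row_w$r, sum((x - mean(x)) * (depth - mean(depth))) /
    sqrt(sum((x - mean(x))^2) * sum((depth - mean(depth))^2)),
  tolerance = 1e-12
  )

  # all-null simulation: per-test flag rate compatible with 5%
  set.seed(4)
  flags <- 0L
  total <- 0L
  for (r in 1:100) {
    tr <- tibble::tibble(genotype = genos, env = "E1", GY = rnorm(n))
    bb <- tibble::tibble(genotype = genos, trait = "depth", blue = rnorm(n))
    cc <- trait_field_correlations(bb, tr, field_traits = "GY")
    flags <- flags + sum(cc$sig_05)
    total <- total + nrow(cc)
  }
  rate <- flags / total
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / total))
})

test_that("Bonferroni effective-test count never exceeds the raw count", {
  cfg <- tiny_config(seed = 5, n_lines = 60)
  g <- simulate_genotypes(cfg)
  field <- simulate_field_trials(cfg, g)
  blues <- tibble::tibble(
    genotype = rep(rownames(g$dosage), 2),
    trait = rep(c("depth", "width"), each = 60),
    blue = rnorm(120)
  )
  ct <- trait_field_correlations(blues, field$trial, field_traits = "GY")
  nit <- attr(ct, "n_indep_traits")
  nie <- attr(ct, "n_indep_envs")
  expect_lte(nit, 2)
  expect_lte(nie, length(unique(field$trial$env)))
  expect_lte(
    attr(ct, "alpha_bonferroni") * nit * nie, 0.05 + 1e-12
  )
})

test_that("multi-trait R matches its algebraic identities", {
  set.seed(6)
  d <- tibble::tibble(
    y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40)
  )
  d$y <- d$x1 * 0.5 + rnorm(40, 0, 0.5)
  # single predictor: R = |r|
  expect_equal(as.numeric(multi_trait_R(d, "y", "x1")), abs(cor(d$y, d$x1)),
    tolerance = 1e-12
  )
  # response among predictors: R = 1
  d$yy <- d$y
  expect_equal(as.numeric(multi_trait_R(d, "y", c("x1", "yy"))), 1,
    tolerance = 1e-10
  )
  # R^2 equals 1 - RSS/TSS
  f <- lm(y ~ x1 + x2 + x3, data = d)
  r2 <- 1 - sum(residuals(f)^2) / sum((d$y - mean(d$y))^2)
  R <- multi_trait_R(d, "y", c("x1", "x2", "x3"))
  expect_equal(attr(R, "r_squared"), r2, tolerance = 1e-10)
  # collinear predictors: aliased column logged, fit still returned
  d$x1b <- d$x1
  Rc <- multi_trait_R(d, "y", c("x1", "x1b", "x2"))
  expect_gt(length(attr(Rc, "aliased")), 0)
  expect_error(multi_trait_R(d[1:3, ], "y", c("x1", "x2", "x3")), "observations")
})

test_that("per-environment SNP effects recover flat and null reaction norms", {
  qtl <- tibble::tibble(
    marker = 20, trait = "biomass", effect = 0, a = 400, b = 0,
    covariate = "w_stress"
  )
  cfg <- tiny_config(
    seed = 7, n_lines = 150, qtl_spec = qtl,
    field_sigma2_g = 1e4, field_sigma2_e = 2e4
  )
  g <- simulate_genotypes(cfg)
  gq <- qc_markers(g)
  K <- compute_kinship(gq)
  field <- simulate_field_trials(cfg, g)
  causal <- g$map$marker[20]
  skip_if_not(causal %in% colnames(gq$dosage))
  tc <- phenology_correct(field$trial)
  eff <- snp_effect_by_environment(tc, gq, causal, "GYC", kinship = K)
  expect_equal(nrow(eff), nrow(cfg$environments))
  # flat norm: mean estimate within a few pooled SE of a = 400 (QC recodes
  # onto the minor allele, which may flip the sign convention)
  flipped <- !isTRUE(all.equal(
    unname(gq$dosage[, causal]), unname(g$dosage[, causal])
  ))
  truth_a <- if (flipped) -400 else 400
  pooled_se <- sqrt(mean(eff$se^2) / nrow(eff))
  expect_lt(abs(mean(eff$effect) - truth_a), 2 * pooled_se * 3)

  # null marker: estimates centered on zero
  null_marker <- gq$map$marker[gq$map$chrom == "c2"][5]
  eff0 <- snp_effect_by_environment(tc, gq, null_marker, "GYC", kinship = K)
  pooled0 <- sqrt(mean(eff0$se^2) / nrow(eff0))
  expect_lt(abs(mean(eff0$effect)), 3 * pooled0 * 3)

  # identically simulated environments give identical estimates
  t2 <- tc[tc$env == tc$env[1], ]
  t2b <- t2
  t2b$env <- "COPY"
  eff2 <- snp_effect_by_environment(dplyr::bind_rows(t2, t2b), gq, causal,
    "GYC",
    kinship = K
  )
  expect_equal(eff2$effect[1], eff2$effect[2], tolerance = 1e-12)
})

test_that("effect-covariate regression recovers slopes and handles edge cases", {
  # exactly linear effects: r2 = 1; constant effects: slope 0, r2 0
  eff <- tibble::tibble(
    env = sprintf("E%02d", 1:12), n = 100,
    effect = 0.2 - 0.5 * seq(0.05, 1, length.out = 12),
    se = 0.01, p = 0.01
  )
  covs <- tibble::tibble(
    env = sprintf("E%02d", 1:12),
    w_stress = seq(0.05, 1, length.out = 12)
  )
  rr <- qtl_env_regression(eff, covs)
  expect_equal(rr$r_squared, 1, tolerance = 1e-10)
  expect_equal(rr$slope, -0.5, tolerance = 1e-10)

  effc <- eff
  effc$effect <- 0.3
  rrc <- qtl_env_regression(effc, covs)
  expect_equal(rrc$slope, 0, tolerance = 1e-12)
  expect_equal(rrc$r_squared, 0, tolerance = 1e-12)

  # constant covariate skipped
  covs2 <- covs
  covs2$frost <- 5
  rr2 <- qtl_env_regression(eff, covs2)
  expect_false("frost" %in% rr2$covariate)
  expect_equal(attr(rr2, "skipped"), "frost")

  # simulated reaction norm: slope within its 95% CI in >= 18/20 seeds
  hits <- 0L
  for (s in 1:20) {
    set.seed(1200 + s)
    e <- tibble::tibble(
      env = covs$env, n = 100,
      effect = 0.2 - 0.5 * covs$w_stress + rnorm(12, 0, 0.05),
      se = 0.05, p = 0.5
    )
    r <- qtl_env_regression(e, covs)
    f <- summary(lm(e$effect ~ covs$w_stress))
    ci <- f$coefficients[2, 1] + c(-1, 1) * qt(0.975, 10) * f$coefficients[2, 2]
    if (-0.5 >= ci[1] && -0.5 <= ci[2]) hits <- hits + 1L
    expect_equal(r$slope, unname(f$coefficients[2, 1]), tolerance = 1e-10)
  }
  expect_gte(hits, 18L)
})

test_that("era trends recover a selection signal and stay calibrated under the null", {
  # 5-point toy equals the closed-form least-squares slope
  blues <- tibble::tibble(
    genotype = paste0("g", 1:5), trait = "depth",
    blue = c(2, 4, 5, 4, 6)
  )
  yrs <- tibble::tibble(genotype = paste0("g", 1:5),
                        year = c(1950, 1960, 1970, 1980, 1990))
  tr <- era_trends(blues, yrs, n_traits_tested = 1, min_n = 5)
  x <- yrs$year
  y <- blues$blue
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(tr$slope, slope_hand, tolerance = 1e-12)

  # simulated decline of -0.003/yr over 80 years, low noise, 20 seeds
  hits <- 0L
  for (s in 1:20) {
    set.seed(1300 + s)
    n <- 200
    yr <- sample(1940:2020, n, replace = TRUE)
    bl <- tibble::tibble(
      genotype = sprintf("g%03d", 1:n), trait = "root_biomass",
      blue = 1.5 - 0.003 * (yr - 1980) + rnorm(n, 0, 0.05)
    )
    yt <- tibble::tibble(genotype = sprintf("g%03d", 1:n), year = yr)
    res <- era_trends(bl, yt, n_traits_tested = 12)
    if (res$slope < 0 && res$p < 0.05 / 12) hits <- hits + 1L
  }
  expect_gte(hits, 18L)

  # null calibration: rejection rate at alpha = 0.05 near 5%
  set.seed(9)
  rej <- vapply(1:100, function(i) {
    n <- 60
    yr <- sample(1940:2020, n, replace = TRUE)
    bl <- tibble::tibble(
      genotype = sprintf("g%03d", 1:n), trait = "t", blue = rnorm(n)
    )
    era_trends(bl, tibble::tibble(genotype = bl$genotype, year = yr),
      n_traits_tested = 1
    )$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 100))

  expect_error(
    era_trends(blues, tibble::tibble(genotype = paste0("g", 1:5), year = 1980)),
    "equal"
  )
})
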