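test_that("sensor interpolation is exact at sensors and accurate on gradients", {
  sensors <- tibble::tibble(
    x = c(1, 5, 9, 3, 7), y = c(1, 2, 8, 9, 5), value = 21.8
  )
  q <- tibble::tibble(x = c(2, 4, 6), y = c(3, 3, 7))
  out <- interpolate_sensors(sensors, q)
  expect_equal(out$value, rep(21.8, 3), tolerance = 1e-12)

  # exactness at a sensor coordinate
  sensors$value <- c(20, 21, 22, 23, 24)
  at_sensor <- interpolate_sensors(sensors, sensors[3, c("x", "y")])
  expect_equal(at_sensor$value, 22, tolerance = 1e-12)

  # linear gradient, dense sensor grid: LOO RMSE below 5% of range
  grid <- expand.grid(x = seq(0, 10, by = 0.25), y = seq(0, 10, by = 0.25))
  grid$value <- 15 + 0.4 * grid$x + 0.2 * grid$y
  out2 <- interpolate_sensors(grid, tibble::tibble(x = 5.5, y = 5.5))
  rng <- diff(range(grid$value))
  expect_lt(attr(out2, "loo_rmse") / rng, 0.05)
  grid_k <- expand.grid(x = seq(0, 10, by = 1), y = seq(0, 10, by = 1))
  grid_k$value <- 15 + 0.4 * grid_k$x + 0.2 * grid_k$y
  out3 <- interpolate_sensors(grid_k, tibble::tibble(x = 5.5, y = 5.5),
    method = "kriging"
  )
  expect_lt(attr(out3, "loo_rmse") / diff(range(grid_k$value)), 0.05)

  # conflicting duplicate sensors are rejected
  bad <- tibble::tibble(x = c(1, 1), y = c(1, 1), value = c(1, 2))
  expect_error(interpolate_sensors(bad, q), "conflicting")
})

test_that("trajectory smoothing preserves lines and reduces noise", {
  # exactly linear series: smoother reproduces it
  ser <- tibble::tibble(day = seq(2, 20, by = 2), value = 1 + 0.5 * seq(2, 20, by = 2))
  out <- smooth_trajectories(ser, window = 5, at_day = 10)
  expect_equal(out$smoothed, ser$value, tolerance = 1e-10)
  expect_equal(attr(out, "value_at"), 1 + 0.5 * 10, tolerance = 1e-10)

  # constant series stays constant
  serc <- tibble::tibble(day = 1:8, value = 3.3)
  outc <- smooth_trajectories(serc)
  expect_equal(outc$smoothed, rep(3.3, 8), tolerance = 1e-12)

  # noisy line: smoothed RMSE to truth beats raw RMSE
  set.seed(2)
  better <- 0
  for (r in 1:20) {
    days <- 1:15
    truth <- 2 + 0.3 * days
    obs <- truth + rnorm(15, 0, 0.5)
    sm <- smooth_trajectories(tibble::tibble(day = days, value = obs))
    if (sqrt(mean((sm$smoothed - truth)^2)) < sqrt(mean((obs - truth)^2))) {
      better <- better + 1
    }
  }
  expect_gte(better, 18)

  # short series falls back to a global fit with a warning
  expect_warning(
    out_s <- smooth_trajectories(tibble::tibble(day = 1:3, value = c(1, 2, 3)),
      window = 5
    ),
    "global"
  )
  expect_true(attr(out_s, "fallback"))
  expect_error(smooth_trajectories(tibble::tibble(day = 1, value = 1)), "two")
})

test_that("outlier rules remove failed plants and extreme genotypes", {
  cfg <- tiny_config(seed = 30, outlier_frac = 0.03, n_lines = 100,
    traits = list(biomass = list(mean = 3, sigma2_g = 0.05, sigma2_e = 0.05)))
  g <- simulate_genotypes(cfg)
  sim <- simulate_platform_plots(cfg, g)
  filt <- filter_outliers(sim$plots, trait = NULL)
  expect_true(all(filt$plots$biomass >= 0.5))
  expect_setequal(filt$log$plot_id, sim$truth$outlier_plots)
  expect_true(all(grepl("biomass<0.5", filt$log$rule)))

  # a plot with root biomass 0.4 g goes under the 0.5 g rule
  p <- sim$plots
  p$root_biomass <- 2
  p$root_biomass[5] <- 0.4
  f2 <- filter_outliers(p, trait = NULL)
  expect_true(p$plot_id[5] %in% f2$log$plot_id)

  # clean table + loose rules: identity, empty log
  clean <- filter_outliers(filt$plots, trait = NULL)
  expect_identical(clean$plots, filt$plots)
  expect_equal(nrow(clean$log), 0)

  # residual rule catches a gross error on a replicated (check) plot;
  # a singleton genotype's outlier is confounded with its genetic effect
  p3 <- filt$plots
  i_chk <- which(p3$is_check)[1]
  p3$biomass[i_chk] <- p3$biomass[i_chk] + 50
  f3 <- filter_outliers(p3, trait = "biomass", resid_k = 4)
  expect_true(p3$plot_id[i_chk] %in% f3$log$plot_id)

  # genotype-level bounds on adjusted means
  bl <- tibble::tibble(
    genotype = c("a", "b", "c"), trait = "convex_hull",
    blue = c(30000, 41000, 12000)
  )
  fg <- filter_genotype_bounds(bl)
  expect_equal(fg$blues$genotype, c("a", "c"))
  expect_equal(fg$log$genotype, "b")

  expect_error(
    filter_outliers(tibble::tibble(
      plot_id = "P1", genotype = "g", row = 1, col = 1, biomass = 0.1
    )),
    "every plot"
  )
})

test_that("degenerate noise-free data give exact BLUEs and zero residual variance", {
  cfg <- tiny_config(
    seed = 31,
    traits = list(biomass = list(mean = 3, sigma2_g = 0.5, sigma2_e = 0)),
    spatial_amplitude = 0, sigma2_block = 0, beta_temp = 0
  )
  g <- simulate_genotypes(cfg)
  sim <- simulate_platform_plots(cfg, g)
  fit <- fit_spatial_model(sim$plots, "biomass", genotype_as = "fixed")
  truth <- sim$truth$genetic_values
  m <- dplyr::inner_join(fit$blues, truth, by = "genotype")
  # equal up to a common intercept
  expect_lt(sd(m$blue - m$value), 1e-6)
  expect_lt(fit$varcomp$residual, 1e-6)

  # BLUE invariance: shifting every plot by c shifts every BLUE by c
  p2 <- sim$plots
  p2$biomass <- p2$biomass + 7.5
  fit2 <- fit_spatial_model(p2, "biomass", genotype_as = "fixed")
  expect_equal(fit2$blues$blue, fit$blues$blue + 7.5, tolerance = 1e-6)
})

test_that("fitted surface is centered and refitting fitted values kills noise", {
  cfg <- tiny_config(seed = 32, spatial_amplitude = 0.5)
  g <- simulate_genotypes(cfg)
  sim <- simulate_platform_plots(cfg, g)
  fit <- fit_spatial_model(sim$plots, "biomass")
  expect_lt(abs(mean(fit$surface)), 0.05)
  expect_lt(abs(sum(fit$residuals)), 1e-6)

  refit_data <- fit$data
  refit_data$biomass <- fit$gam$fitted.values
  refit <- fit_spatial_model(refit_data, "biomass")
  expect_lt(refit$varcomp$residual, 1e-4)

  expect_error(fit_spatial_model(sim$plots, "no_such_trait"), "not found")
  one_geno <- sim$plots[sim$plots$genotype == sim$plots$genotype[1], ]
  expect_error(fit_spatial_model(one_geno, "biomass"), "two genotypes")
})

test_that("spatial adjustment beats raw plot means under a smooth surface", {
  wins <- 0L
  for (s in 1:20) {
    cfg <- tiny_config(
      seed = 800 + s, n_lines = 80,
      greenhouse = list(n_blocks = 4, n_checks = 6, n_rep = 2,
                        n_experiments = 1),
      traits = list(biomass = list(mean = 3, sigma2_g = 0.3, sigma2_e = 0.05)),
      spatial_amplitude = 0.8, sigma2_block = 0.1
    )
    g <- simulate_genotypes(cfg)
    sim <- simulate_platform_plots(cfg, g)
    truth <- sim$truth$genetic_values
    fit <- fit_spatial_model(sim$plots, "biomass")
    m <- dplyr::inner_join(fit$blues, truth, by = "genotype")
    raw <- sim$plots |>
      dplyr::group_by(genotype) |>
      dplyr::summarise(raw = mean(biomass)) |>
      dplyr::inner_join(truth, by = "genotype")
    if (cor(m$blue, m$value) > cor(raw$raw, raw$value)) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("generalized heritability tracks the balanced-design closed form", {
  # H2 ~ sigma2_g / (sigma2_g + sigma2_e / r) for r replicates, no spatial terms
  h2_err <- numeric(6)
  i <- 0
  for (s in 1:3) {
    for (r in c(2, 3)) {
      i <- i + 1
      cfg <- tiny_config(
        seed = 900 + 10 * r + s, n_lines = 100,
        greenhouse = list(n_blocks = 1, n_checks = 0, n_rep = r,
                          n_experiments = 1),
        traits = list(biomass = list(mean = 3, sigma2_g = 0.4, sigma2_e = 0.3)),
        spatial_amplitude = 0, sigma2_block = 0, beta_temp = 0
      )
      g <- simulate_genotypes(cfg)
      sim <- simulate_platform_plots(cfg, g)
      fit <- fit_spatial_model(sim$plots, "biomass", genotype_as = "random")
      h2 <- generalized_heritability(fit)
      # realized genetic variance differs from sigma2_g through K; use the
      # realized truth to form the closed-form reference
      truth <- sim$truth$genetic_values
      s2g <- var(truth$value)
      ref <- s2g / (s2g + 0.3 / r)
      h2_err[i] <- abs(as.numeric(h2) - ref)
    }
  }
  expect_lt(mean(h2_err), 0.05)

  # null: sigma2_g = 0 gives H2 near 0 (well-replicated design);
  # noise-free gives H2 near 1
  h2_null <- vapply(1:10, function(s) {
    cfg <- tiny_config(
      seed = 950 + s, n_lines = 300,
      greenhouse = list(n_blocks = 1, n_checks = 0, n_rep = 4,
                        n_experiments = 1),
      traits = list(biomass = list(mean = 3, sigma2_g = 0, sigma2_e = 0.3)),
      spatial_amplitude = 0, sigma2_block = 0, beta_temp = 0
    )
    g <- simulate_genotypes(cfg)
    sim <- simulate_platform_plots(cfg, g)
    as.numeric(generalized_heritability(
      fit_spatial_model(sim$plots, "biomass", genotype_as = "random")
    ))
  }, numeric(1))
  expect_lt(mean(h2_null), 0.05)

  cfg1 <- tiny_config(
    seed = 960, n_lines = 100,
    greenhouse = list(n_blocks = 1, n_checks = 0, n_rep = 2, n_experiments = 1),
    traits = list(biomass = list(mean = 3, sigma2_g = 0.5, sigma2_e = 1e-6)),
    spatial_amplitude = 0, sigma2_block = 0, beta_temp = 0
  )
  g1 <- simulate_genotypes(cfg1)
  sim1 <- simulate_platform_plots(cfg1, g1)
  h2_perfect <- generalized_heritability(
    fit_spatial_model(sim1$plots, "biomass", genotype_as = "random")
  )
  expect_gt(as.numeric(h2_perfect), 0.98)

  # fixed-genotype fit refuses to report heritability
  fitf <- fit_spatial_model(sim1$plots, "biomass", genotype_as = "fixed")
  expect_error(generalized_heritability(fitf), "random")
})

test_that("H2 is monotone in the simulated genetic variance", {
  grid <- c(0.05, 0.2, 0.5, 1.0)
  mean_h2 <- vapply(seq_along(grid), function(gi) {
    mean(vapply(1:5, function(s) {
      cfg <- tiny_config(
        seed = 1000 + 10 * gi + s, n_lines = 80,
        greenhouse = list(n_blocks = 2, n_checks = 4, n_rep = 2,
                          n_experiments = 1),
        traits = list(biomass = list(mean = 3, sigma2_g = grid[gi],
                                     sigma2_e = 0.3))
      )
      g <- simulate_genotypes(cfg)
      sim <- simulate_platform_plots(cfg, g)
      as.numeric(generalized_heritability(
        fit_spatial_model(sim$plots, "biomass", genotype_as = "random")
      ))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_h2) > -0.02)) # non-decreasing up to seed noise
  expect_gt(mean_h2[4], mean_h2[1])
})

test_that("trait_blues combines experiments and reports heritability", {
  cfg <- tiny_config(
    seed = 33, n_lines = 60,
    greenhouse = list(n_blocks = 3, n_checks = 4, n_rep = 1, n_experiments = 2)
  )
  g <- simulate_genotypes(cfg)
  sim <- simulate_platform_plots(cfg, g)
  bl <- trait_blues(sim$plots)
  expect_setequal(unique(bl$trait), "biomass")
  expect_equal(nrow(bl), length(unique(sim$plots$genotype)))
  expect_true(all(bl$n_experiments == 2))
  h2 <- attr(bl, "h2")
  expect_true(all(h2$H2 >= 0 & h2$H2 <= 1))
  # correlation with truth is strong
  m <- dplyr::inner_join(bl, sim$truth$genetic_values, by = "genotype")
  expect_gt(cor(m$blue, m$value), 0.7)
})
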