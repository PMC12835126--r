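# Shared small Monte-Carlo settings: the zig-zag layout in the rodent set
# needs sampling; one seeded point cloud is reused across the whole grid.
fit_mc <- mc_settings(2e5, seed = 11)

test_that("noise-free on-grid truth is recovered exactly", {
  truth <- dual_observer_params(42, 1.64, 2122)
  dat <- simulate_yields(truth, rodent_config_set(), n_recordings = 1,
                         noise = "none", mc = fit_mc)
  fit <- fit_dual_observer(dat, mc = fit_mc)
  expect_equal(unname(coef(fit)), c(42, 1.64, 2122), tolerance = 1e-6)
  expect_equal(fit$similarity, 1, tolerance = 1e-12)
  expect_identical(fit$diagnostics$n_ties, 1L)
  # predictions reproduce the data and residuals vanish
  expect_equal(unname(fit$predicted), dat$configs$median_upc, tolerance = 1e-9)
  expect_equal(residuals(fit), rep(0, 5), tolerance = 1e-9)
})

test_that("cosine similarity makes the fit scale-invariant", {
  truth <- dual_observer_params(42, 1.64, 2122)
  dat <- simulate_yields(truth, rodent_config_set(), n_recordings = 1,
                         noise = "none", mc = fit_mc)
  scaled <- dat
  scaled$observations$units_per_channel <-
    10 * scaled$observations$units_per_channel
  scaled <- yield_data(scaled$observations, scaled$layouts)
  fit <- fit_dual_observer(scaled, mc = fit_mc)
  expect_equal(fit$params$r_obs, 42)
  expect_equal(fit$params$g, 1.64, tolerance = 1e-9)
  expect_equal(fit$params$p_single, 21220, tolerance = 1e-6)
})

test_that("the grid argmax is invariant to configuration order", {
  truth <- dual_observer_params(42, 1.64, 2122)
  dat <- simulate_yields(truth, rodent_config_set(), n_recordings = 3,
                         noise = "lognormal", sigma = 0.2, seed = 5,
                         mc = fit_mc)
  fit1 <- fit_dual_observer(dat, mc = fit_mc)
  perm <- sample(nrow(dat$observations))
  dat2 <- yield_data(dat$observations[perm, ], dat$layouts)
  fit2 <- fit_dual_observer(dat2, mc = fit_mc)
  expect_identical(coef(fit1), coef(fit2))
  expect_identical(fit1$similarity, fit2$similarity)
})

test_that("off-grid truth lands within one grid step", {
  # linear-only configuration set: volumes are analytic, so the only
  # discretisation is the grid itself
  configs <- lapply(c(12, 24, 48, 96), function(d) {
    linear_layout(1536 / d, d)
  })
  truth <- dual_observer_params(41.6, 1.57, 1800)
  dat <- simulate_yields(truth, configs, n_recordings = 1, noise = "none",
                         mc = fit_mc)
  fit <- fit_dual_observer(dat, mc = fit_mc)
  expect_lte(abs(fit$params$r_obs - 41.6), 1)
  expect_lte(abs(fit$params$g - 1.57), 0.011)
})

test_that("degenerate datasets are rejected with clear errors", {
  lay <- list(a = linear_layout(8, 10, name = "a"),
              b = linear_layout(8, 20, name = "b"),
              c = linear_layout(8, 40, name = "c"))
  obs <- data.frame(config_label = c("a", "b", "c"), recording_id = "r1",
                    units_per_channel = 0)
  expect_error(fit_dual_observer(yield_data(obs, lay), mc = fit_mc),
               "similarity is undefined")
  obs2 <- data.frame(config_label = c("a", "b"), recording_id = "r1",
                     units_per_channel = c(1, 2))
  expect_error(fit_dual_observer(yield_data(obs2, lay[1:2]), mc = fit_mc),
               "at least 3")
  obs3 <- obs
  obs3$units_per_channel <- c(1, NaN, 2)
  expect_error(yield_data(obs3, lay), "non-finite")
  obs4 <- obs
  obs4$units_per_channel <- c(1, -0.2, 2)
  expect_error(yield_data(obs4, lay), "non-negative")
})

test_that("yields CSV round-trips and accepts the raw-count dialect", {
  truth <- dual_observer_params(30, 1.3, 900)
  configs <- lapply(c(24, 48, 96), function(d) linear_layout(16, d))
  dat <- simulate_yields(truth, configs, n_recordings = 2, seed = 3,
                         mc = fit_mc)
  path <- tempfile(fileext = ".csv")
  write_yields(dat, path)
  back <- read_yields(path)
  expect_equal(back$configs$median_upc, dat$configs$median_upc)
  expect_equal(back$configs$m, dat$configs$m)
  expect_equal(back$configs$d_nn, dat$configs$d_nn)

  # raw n_units divided by n_channels at ingest
  df <- utils::read.csv(path)
  df$n_units <- df$units_per_channel * df$n_channels
  df$units_per_channel <- NULL
  path2 <- make_temp_yields_csv(df)
  back2 <- read_yields(path2)
  expect_equal(back2$configs$median_upc, dat$configs$median_upc)

  # missing columns are named
  df$n_units <- NULL
  path3 <- make_temp_yields_csv(df)
  expect_error(read_yields(path3), "units_per_channel")
})

test_that("median over recordings uses the even-count midpoint", {
  lay <- list(a = linear_layout(8, 10, name = "a"),
              b = linear_layout(8, 20, name = "b"),
              c = linear_layout(8, 40, name = "c"))
  obs <- data.frame(
    config_label = rep(c("a", "b", "c"), each = 4),
    recording_id = rep(sprintf("r%d", 1:4), 3),
    units_per_channel = c(1, 2, 3, 10, rep(1, 8)))
  dat <- yield_data(obs, lay)
  expect_equal(dat$configs$median_upc[dat$configs$config_label == "a"], 2.5)
})

test_that("the report reproduces table-style derived quantities", {
  truth <- dual_observer_params(42, 1.64, 2122)
  dat <- simulate_yields(truth, rodent_config_set(), n_recordings = 1,
                         noise = "none", mc = fit_mc)
  fit <- fit_dual_observer(dat, mc = fit_mc)
  rep32 <- fit_report(fit, m_values = 32)
  row <- rep32$per_M[[1]]
  expect_identical(row$D_opt_label, "37 um")
  expect_equal(row$E_opt_approx, 1.4064)
  expect_equal(row$opt_units_per_channel, 0.9262, tolerance = 1e-4)
  expect_identical(row$regime, "interior_optimum")
  # experimental comparators come from the dataset medians
  expect_equal(rep32$experimental$best_pitch_um, 48)
  expect_equal(rep32$experimental$high_density_units_per_channel,
               dat$configs$median_upc[1])
  expect_equal(rep32$experimental$improvement_vs_high_density,
               row$opt_units_per_channel / dat$configs$median_upc[1])
  # JSON serialisation round-trips the headline numbers
  path <- tempfile(fileext = ".json")
  write_fit_report(rep32, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$params$R_um, 42)
  expect_equal(parsed$per_M$opt_units_per_channel, row$opt_units_per_channel)
})

test_that("a g <= 1 fit reports the boundary optimum", {
  # thalamus-like truth on a linear series, searched on a focused grid
  truth <- dual_observer_params(15, 0.83, 47639)
  configs <- lapply(c(12, 24, 48, 96), function(d) linear_layout(1536 / d, d))
  dat <- simulate_yields(truth, configs, n_recordings = 1, noise = "none",
                         mc = fit_mc)
  fit <- fit_dual_observer(dat, grid = grid_spec(5, 40, 1, 0.5, 1.5, 0.01),
                           mc = fit_mc)
  expect_equal(fit$params$r_obs, 15)
  expect_equal(fit$params$g, 0.83, tolerance = 1e-9)
  rep32 <- fit_report(fit, m_values = 32)
  expect_identical(rep32$per_M[[1]]$regime, "boundary_g_le_1")
  expect_identical(rep32$per_M[[1]]$D_opt_label, ">= 15 um")
  expect_identical(rep32$per_M[[1]]$E_opt_approx, 1)
})

test_that("fit methods: predict, plot and simulate", {
  truth <- dual_observer_params(42, 1.64, 2122)
  dat <- simulate_yields(truth, rodent_config_set(), n_recordings = 1,
                         noise = "none", mc = fit_mc)
  fit <- fit_dual_observer(dat, mc = fit_mc)
  # linear-array predictions match the direct model evaluation
  nd <- data.frame(m = c(32, 16), pitch_um = c(48, 96))
  expect_equal(unname(predict(fit, nd)),
               c(units_per_channel(32, 42, 48, 1.64, 2122),
                 units_per_channel(16, 42, 96, 1.64, 2122)),
               tolerance = 1e-9)
  # layout-list predictions run through the hybrid volume route
  expect_equal(unname(predict(fit, list(linear_layout(32, 48)))),
               units_per_channel(32, 42, 48, 1.64, 2122), tolerance = 1e-9)
  # simulate() returns replicate datasets over the fitted configurations
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_identical(sims[[1]]$configs$config_label, dat$configs$config_label)
  expect_false(identical(sims[[1]]$observations$units_per_channel,
                         sims[[2]]$observations$units_per_channel))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_no_error(plot(fit))
})
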