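test_that("noise-free wells follow the logistic-with-lag closed form", {
  p <- sim_params(doubling_time_min = 25, lag_min = 60,
                  carrying_capacity_od = 1, od_per_cell = 3e-8,
                  background_od = 0.1, duration_min = 300)
  ws <- simulate_well(p, 1e4)
  tt <- ws$times
  K <- 1 / 3e-8
  mu <- log(2) / 25
  n <- K / (1 + (K / 1e4 - 1) * exp(-mu * pmax(tt - 60, 0)))
  expect_equal(ws$od, 0.1 + 3e-8 * n)
  # flat at background until the lag ends
  expect_true(all(abs(ws$od[tt <= 60] - ws$od[1]) < 1e-6))
  # empty wells read pure background
  expect_equal(simulate_well(p, 0)$od, rep(0.1, length(tt)))
})

test_that("OD saturates at background + carrying capacity", {
  p <- sim_params(doubling_time_min = 20, lag_min = 0,
                  carrying_capacity_od = 0.8, duration_min = 1440)
  ws <- simulate_well(p, 1e5)
  expect_lt(max(ws$od), 0.9 + 1e-9)
  expect_equal(max(ws$od), 0.9, tolerance = 1e-3)
  expect_true(all(diff(ws$od) >= 0))
})

test_that("multiplicative noise is unit-mean with the requested CV", {
  p <- sim_params(noise_cv = 0.05, lag_min = 0, duration_min = 1440,
                  interval_min = 1)
  ws <- with_seed(3, simulate_well(p, 0))  # background only: pure noise
  ratio <- ws$od / 0.1
  expect_lt(abs(mean(ratio) - 1), 0.01)
  expect_lt(abs(sd(ratio) / mean(ratio) - 0.05), 0.01)
})

test_that("simulation is deterministic under a seed and restores the RNG", {
  p <- sim_params(noise_cv = 0.05)
  a <- simulate_well(p, 1000, seed = 123)
  b <- simulate_well(p, 1000, seed = 123)
  expect_identical(a, b)
  set.seed(42); state <- .Random.seed
  invisible(simulate_well(p, 1000, seed = 9))
  expect_identical(.Random.seed, state)
  s1 <- simulate_dilution_series(p, 1e8, exponents = 0:-2, replicates = 2,
                                 seed = 55)
  s2 <- simulate_dilution_series(p, 1e8, exponents = 0:-2, replicates = 2,
                                 seed = 55)
  expect_identical(s1$run$wells, s2$run$wells)
  expect_identical(s1$truth, s2$truth)
})

test_that("dilution-series seeding is Poisson with the stated lambda", {
  p <- sim_params()
  sim <- simulate_dilution_series(p, stock_cfu_per_ml = 2e6,
                                  exponents = -1, replicates = 96, seed = 8)
  # lambda = 2e6 * 10^-1 * 5 / 1000 = 1000 cells per well
  expect_equal(unique(sim$truth$lambda), 1000)
  m <- mean(sim$truth$true_cells)
  expect_lt(abs(m - 1000), 3 * sqrt(1000 / 96))
  expect_equal(nrow(sim$layout), 96)
  expect_error(simulate_dilution_series(p, 1e6, exponents = 0:-7,
                                        replicates = 13), "96 wells")
})

test_that("strain presets carry the published thresholds and reject typos", {
  expect_equal(strain_preset("OP50-like")$doubling_time_min, 25)
  expect_equal(strain_preset("BY4742-like")$doubling_time_min, 90)
  lgg <- strain_preset("LGG-like")
  expect_equal(lgg$doubling_time_min, 60)
  expect_equal(lgg$threshold_od, 0.15)
  expect_equal(strain_preset("OP50-like")$threshold_od, 0.3)
  expect_equal(strain_preset("OP50-like", noise_cv = 0.05)$noise_cv, 0.05)
  expect_error(strain_preset("OP51"), "available presets")
})

test_that("heat-treatment truth respects the kill and lag parameters", {
  p <- strain_preset("OP50-like")
  sim <- simulate_heat_treatment(p, stock_cfu_per_ml = 2e8,
                                 kill_fraction = 0.5,
                                 lag_extension_min = 30, replicates = 6,
                                 dilution_exponent = -2, seed = 2)
  tr <- sim$truth[sim$truth$sample_id == "treated", ]
  ct <- sim$truth[sim$truth$sample_id == "control", ]
  expect_true(all(tr$true_cells <= tr$cells_before_treatment))
  expect_equal(unique(tr$lag_extension_min), 30)
  expect_equal(ct$true_cells, ct$cells_before_treatment)
  # binomial thinning: treated mean near half the pre-treatment mean
  expect_lt(abs(mean(tr$true_cells) / mean(tr$cells_before_treatment) - 0.5),
            0.05)
  # full kill leaves every treated well sterile
  dead <- simulate_heat_treatment(p, 2e8, kill_fraction = 1,
                                  lag_extension_min = 0, replicates = 3,
                                  dilution_exponent = -2, seed = 2)
  expect_true(all(dead$truth$true_cells[dead$truth$sample_id == "treated"] == 0))
})
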