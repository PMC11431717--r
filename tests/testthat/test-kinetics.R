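test_that("baseline correction is the median of the initial readings", {
  ws <- well_series("A1", seq(0, 20, 5), c(0.05, 0.05, 0.05, 0.10, 0.30))
  bc <- baseline_correct(ws, n_initial = 3)
  expect_equal(bc$baseline_od, 0.05)
  expect_equal(bc$series$od, c(1e-4, 1e-4, 1e-4, 0.05, 0.25))

  flat <- well_series("A1", seq(0, 20, 5), rep(0.08, 5))
  expect_equal(baseline_correct(flat, 3)$series$od, rep(1e-4, 5))

  two <- well_series("A1", c(0, 5), c(0.07, 0.09))
  expect_equal(baseline_correct(two, 1)$baseline_od, 0.07)
  expect_error(baseline_correct(two, 2), "n_initial")
})

test_that("threshold crossing matches the closed-form inversion", {
  tt <- seq(0, 300, 5)
  ws <- well_series("A1", tt, 0.01 * 2^(tt / 30))
  # exact inversion: 0.01 * 2^(t/30) = 0.3 at t = 30*log2(30)
  expect_lt(abs(threshold_crossing(ws, 0.3) - 30 * log2(30)), 5)

  flat <- well_series("A1", tt, rep(0.05, length(tt)))
  expect_true(is.na(threshold_crossing(flat, 0.3)))

  high <- well_series("A1", c(0, 5, 10), c(0.4, 0.5, 0.6))
  expect_equal(threshold_crossing(high, 0.3), 0)
})

test_that("doubling time recovers the generating Td within 1% on exponentials", {
  for (td in c(25, 90)) {
    p <- exp_params(td, duration_min = if (td == 25) 600 else 1440)
    ws <- simulate_well(p, 1000)
    fit <- doubling_time(ws)
    expect_false(fit$no_growth)
    expect_lt(abs(fit$doubling_time_min - td) / td, 0.01)
    expect_gt(fit$r_squared, 0.999)
  }
  flat <- well_series("A1", seq(0, 100, 5), rep(0.1, 21))
  expect_true(doubling_time(flat)$no_growth)
})

test_that("tangent lag recovers an inserted lag when the background is known", {
  cfg <- fit_config(background = 0.1)
  p0 <- sim_params(doubling_time_min = 25, lag_min = 0)
  f0 <- fit_growth(simulate_well(p0, 5000), 0.3, cfg)
  expect_lt(f0$lag_min, 5)  # no inserted lag: tangent meets the inoculum level near t = 0

  p60 <- sim_params(doubling_time_min = 25, lag_min = 60)
  f60 <- fit_growth(simulate_well(p60, 5000), 0.3, cfg)
  expect_lt(abs(f60$lag_min - 60), 5)
})

test_that("doubling the inoculum shifts the crossing by Td and leaves lag unchanged", {
  cfg <- fit_config(background = 0.1)
  p <- sim_params(doubling_time_min = 25, lag_min = 60)
  f1 <- fit_growth(simulate_well(p, 4000, "A1"), 0.3, cfg)
  f2 <- fit_growth(simulate_well(p, 8000, "A2"), 0.3, cfg)
  expect_lt(abs((f1$crossing_min - f2$crossing_min) - 25), 5)
  expect_lt(abs(f1$lag_min - f2$lag_min), 5)
})

test_that("crossing time is strictly decreasing in the inoculum", {
  p <- sim_params(doubling_time_min = 25, lag_min = 60)
  crossings <- vapply(c(10, 100, 1000, 1e4, 1e5), function(n0) {
    fit_growth(simulate_well(p, n0), 0.3)$crossing_min
  }, numeric(1))
  expect_true(all(diff(crossings) < 0))
})

fake_fit <- function(crossing, td = 25, censored = FALSE) {
  structure(list(well_id = "x", crossing_min = crossing, censored = censored,
                 doubling_time_min = td, duration_min = 1440),
            class = "growth_fit")
}

test_that("relative biomass follows the time-to-threshold algebra", {
  a <- fake_fit(300)
  expect_equal(relative_biomass(a, a), 1)
  expect_equal(relative_biomass(fake_fit(275), a), 2)
  expect_equal(relative_biomass(fake_fit(300 + log2(10) * 25), a), 0.1)
  expect_error(relative_biomass(fake_fit(NA, censored = TRUE), a), "censored")
  expect_warning(relative_biomass(fake_fit(275, td = 40), a), "20%")
})

test_that("fit_growth composes the pieces and labels degenerate wells", {
  p <- strain_preset("OP50-like")
  f <- fit_growth(simulate_well(p, 1000), 0.3)
  expect_s3_class(f, "growth_fit")
  expect_false(f$censored)
  expect_false(f$no_growth)
  expect_gt(f$doubling_time_min, 0)
  expect_gte(f$lag_min, 0)
  expect_lt(f$lag_min, f$crossing_min)
  expect_equal(f$threshold_od, 0.3)

  blank <- fit_growth(simulate_well(p, 0), 0.3)
  expect_true(blank$censored)
  expect_true(blank$no_growth)

  sat <- fit_growth(well_series("A1", seq(0, 50, 5), rep(0.5, 11)), 0.3)
  expect_equal(sat$crossing_min, 0)
  expect_true(sat$saturated)
})

test_that("per-well thresholds resolve from layout strain presets", {
  p <- strain_preset("LGG-like")
  run <- plate_run(list(simulate_well(p, 1000, "A1")))
  lay <- as_plate_layout(data.frame(
    well = "A1", sample_id = "S", dilution_exponent = 0, replicate = 1,
    role = "sample", strain_preset = "LGG-like"))
  fits <- fit_plate(run, lay)
  expect_equal(fits$A1$threshold_od, 0.15)
  expect_equal(fit_plate(run, lay, threshold_od = 0.3)$A1$threshold_od, 0.3)
  df <- as.data.frame(fits)
  expect_equal(df$well, "A1")
  expect_false(df$censored)
})
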