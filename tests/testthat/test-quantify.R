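fake_fit <- function(crossing, td = 25, censored = FALSE, duration = 1440) {
  structure(list(well_id = "x", crossing_min = crossing, censored = censored,
                 doubling_time_min = td, duration_min = duration),
            class = "growth_fit")
}

test_that("relative_survival handles detection, censoring and flagging", {
  ref <- fake_fit(200)
  rs <- relative_survival(fake_fit(200 + 25 * log2(100)), ref)
  expect_equal(rs$survival, 0.01)
  expect_false(rs$below_detection)
  expect_false(rs$flagged)

  dense <- relative_survival(fake_fit(150), ref)
  expect_true(dense$flagged)
  expect_equal(dense$survival, 4)

  cens <- relative_survival(fake_fit(NA, censored = TRUE), ref)
  expect_true(cens$below_detection)
  expect_true(is.na(cens$survival))
  expect_equal(cens$upper_bound, 2^(-(1440 - 200) / 25))

  expect_error(relative_survival(fake_fit(100), fake_fit(NA, censored = TRUE)),
               "censored")
})

test_that("cfu_per_ml applies the exact x200 conversion at 5 uL", {
  expect_equal(cfu_per_ml(9912.5, 1), 1982500)
  expect_equal(cfu_per_ml(100, 0.5), 10000)
  expect_equal(cfu_per_ml(100, 1, inoculum_volume_uL = 10), 10000)
  expect_error(cfu_per_ml(0, 1), "n_min")
  expect_error(cfu_per_ml(100, 0), "vn")
  expect_error(cfu_per_ml(100, 1, 0), "inoculum")
})

test_that("the decade law holds exactly on a deterministic ladder", {
  cfg <- fit_config(background = 0.1)
  p <- sim_params(doubling_time_min = 25, lag_min = 0,
                  carrying_capacity_od = 1e7, od_per_cell = 3e-8,
                  duration_min = 540)
  lad <- deterministic_ladder(p, n_top = 1315000, exponents = -1:-5)
  fits <- fit_plate(lad$run, lad$layout, threshold_od = 0.3, config = cfg)
  pts <- build_dilution_points(fits, lad$layout)
  cal <- find_linear_range(pts)
  expect_equal(cal$linear_range, c(-1, -5))
  expect_equal(dynamic_range(cal), 5L)
  expect_lt(abs(cal$slope - 1), 0.02)
  expect_gt(cal$r_squared, 0.999)
  # ten-fold dilution steps drop survival by one decade each
  v <- cal$points$survival[order(cal$points$exponent, decreasing = TRUE)]
  expect_equal(v / 10^(0:-4), rep(1, 5), tolerance = 0.05)
})

synthetic_points <- function(survival, exponents = 0:(-length(survival) + 1),
                             n_saturated = 0) {
  structure(data.frame(exponent = exponents, survival = survival,
                       n_detected = 6L,
                       n_saturated = rep_len(n_saturated, length(survival)),
                       n_total = 6L, flagged = FALSE),
            reference_exponent = exponents[1],
            reference_crossing_min = 200, reference_td_min = 25,
            class = c("dilution_points", "data.frame"))
}

test_that("find_linear_range agrees with an independent brute-force search", {
  cases <- list(
    synthetic_points(10^(0:-6)),                        # perfect 7 decades
    synthetic_points(c(1, 1, 0.1, 0.01, 0.001)),        # flat top excluded
    synthetic_points(c(1, 0.1, 0.012, 0.001, 1e-4, 2e-5)), # wobble inside tol
    synthetic_points(c(30, 1, 0.1, 0.01, 0.001),
                     n_saturated = c(6, 0, 0, 0, 0)),   # saturated top point
    synthetic_points(c(1, 0.1, 0.01, NA, 1e-4, 1e-5))   # gap splits the ladder
  )
  for (pts in cases) {
    oracle <- brute_force_range(pts)
    cal <- find_linear_range(pts)
    expect_equal(cal$linear_range, c(oracle$from, oracle$to))
    expect_equal(dynamic_range(cal), oracle$len)
  }
})

test_that("saturated points are excluded from calibration", {
  pts <- synthetic_points(c(30, 1, 0.1, 0.01, 0.001),
                          n_saturated = c(6, 0, 0, 0, 0))
  cal <- find_linear_range(pts)
  expect_equal(cal$linear_range, c(-1, -4))
  expect_false(cal$points$in_linear_range[cal$points$exponent == 0])
  # renormalised so the accepted reference reads exactly 1
  expect_equal(cal$points$survival[cal$points$exponent == -1], 1)
})

test_that("calibration failure raises a classed error with diagnostics", {
  flat <- synthetic_points(c(1, 0.9, 0.8, 0.7, 0.6))
  err <- tryCatch(find_linear_range(flat), error = identity)
  expect_s3_class(err, "platecount_calibration_error")
  expect_true(is.data.frame(err$diagnostics))
  expect_error(find_linear_range(synthetic_points(c(1, 0.1))), "at least 3")
})

test_that("correlate_actual_vs_expected works on the log scale", {
  expect_equal(correlate_actual_vs_expected(10^(6:0), 10^(6:0)), 1)
  expect_error(correlate_actual_vs_expected(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlate_actual_vs_expected(c(1, 2, 0), c(1, 2, 3)), "positive")
})

test_that("quantify_run recovers a noise-free stock within 5%", {
  p <- strain_preset("OP50-like")
  stock <- 2.63e9
  sim <- with_seed(42, simulate_dilution_series(
    p, stock_cfu_per_ml = stock, exponents = 0:-7, replicates = 6))
  # anchor: a simulated spread-plate count at 10^-2 (mean seeded cells)
  n_at_m2 <- mean(sim$truth$true_cells[sim$truth$dilution_exponent == -2])
  q <- quantify_run(sim$run, sim$layout, n_min = n_at_m2, n_min_exponent = -2)
  expect_lt(abs(q$q_cfu_per_ml - stock) / stock, 0.05)
  expect_gte(q$dynamic_range_decades, 5L)
  expect_lt(abs(q$slope - 1), 0.1)
})

test_that("quantify_run recovers a 5%-noise stock within 25%", {
  p <- strain_preset("OP50-like", noise_cv = 0.05)
  stock <- 2.63e9
  sim <- with_seed(202, simulate_dilution_series(
    p, stock_cfu_per_ml = stock, exponents = 0:-7, replicates = 6))
  # first pass (dummy anchor) identifies the accepted reference dilution;
  # the real anchor is the simulated spread-plate count at that dilution
  ref_e <- quantify_run(sim$run, sim$layout, n_min = 1,
                        config = noisy_cfg())$reference_exponent
  n_ref <- mean(sim$truth$true_cells[sim$truth$dilution_exponent == ref_e])
  q <- quantify_run(sim$run, sim$layout, n_min = n_ref, config = noisy_cfg())
  expect_equal(q$reference_exponent, ref_e)
  expect_lt(abs(q$q_cfu_per_ml - stock) / stock, 0.25)
})

test_that("write_quant_json round-trips the headline numbers", {
  pts <- synthetic_points(10^(0:-6))
  cal <- find_linear_range(pts)
  qr <- structure(list(
    sample_id = "S", reference_exponent = cal$reference_exponent,
    linear_range = cal$linear_range, slope = cal$slope,
    intercept = cal$intercept, r = cal$r, r_squared = cal$r_squared,
    n_min = 9912.5, inoculum_volume_uL = 5, q_cfu_per_ml = 1982500,
    dynamic_range_decades = dynamic_range(cal),
    per_dilution = cal$points, reference_td_min = 25), class = "quant_result")
  path <- tempfile(fileext = ".json")
  write_quant_json(qr, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$q_cfu_per_ml, 1982500)
  expect_equal(back$dynamic_range_decades, 7)
  expect_equal(back$n_min, 9912.5)
})
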