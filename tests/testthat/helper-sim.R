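# Shared fixtures: all synthetic, generated in code at test time.

# Recommended analysis settings for noisy runs (3-point median filter plus a
# wider max-slope window); see the methods vignette.
noisy_cfg <- function(background = NULL) {
  fit_config(window_w = 15L, median_filter = TRUE, background = background)
}

# Parameters whose wells stay in the pure exponential regime for the whole
# run (enormous carrying capacity, run stopped before saturation).
exp_params <- function(td, duration_min = 600, ...) {
  sim_params(doubling_time_min = td, lag_min = 0,
             carrying_capacity_od = 1e4, duration_min = duration_min, ...)
}

well_ids <- function(n) as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))[seq_len(n)]

# A dilution ladder with *deterministic* inocula (no Poisson draw), for
# invariants that isolate the time-to-threshold algebra from seeding noise.
deterministic_ladder <- function(params, n_top, exponents, replicates = 1) {
  nw <- length(exponents) * replicates
  ids <- well_ids(nw)
  grid <- expand.grid(replicate = seq_len(replicates), exponent = exponents)
  grid <- grid[order(match(grid$exponent, exponents), grid$replicate), ]
  n0 <- n_top * 10^(grid$exponent - max(exponents))
  wells <- lapply(seq_len(nw), function(i) {
    simulate_well(params, n0[i], well_id = ids[i])
  })
  layout <- as_plate_layout(data.frame(
    well = ids, sample_id = "S", dilution_exponent = grid$exponent,
    replicate = grid$replicate, role = "sample", stringsAsFactors = FALSE))
  list(run = plate_run(wells), layout = layout, n0 = n0)
}

# Independent brute-force re-derivation of the linear-range search, written
# with lm() over explicit index loops; the oracle for find_linear_range().
brute_force_range <- function(points, slope_tol = 0.1, r2_min = 0.99) {
  ok <- is.finite(points$survival) & points$survival > 0
  if (!is.null(points$n_saturated)) ok <- ok & points$n_saturated == 0
  pts <- points[ok, , drop = FALSE]
  pts <- pts[order(pts$exponent, decreasing = TRUE), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(pts))) {
    for (j in seq_len(nrow(pts))) {
      if (j - i < 2) next
      e <- pts$exponent[i:j]
      if (any(diff(e) != -1)) next
      y <- log10(pts$survival[i:j])
      fit <- lm(y ~ e)
      slope <- unname(coef(fit)[2])
      r2 <- cor(e, y)^2
      if (abs(slope - 1) > slope_tol || r2 < r2_min) next
      cand <- list(from = e[1], to = e[length(e)], len = length(e))
      if (is.null(best) || cand$len > best$len ||
          (cand$len == best$len && cand$from > best$from)) {
        best <- cand
      }
    }
  }
  best
}
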