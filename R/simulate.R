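# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generative parameters for synthetic plate runs
#'
#' The simulator grows each well as a logistic curve with lag: the cell count
#' stays at the inoculum until `lag_min`, then follows
#' `N(t) = K / (1 + (K/n0 - 1) exp(-mu (t - lag)))` with `mu = ln 2 / Td` and
#' `K = carrying_capacity_od / od_per_cell`. OD is
#' `background_od + od_per_cell * N(t)`, each reading multiplied by unit-mean
#' lognormal noise of coefficient of variation `noise_cv` (reader noise
#' scales with signal). All generative constants are configuration, none are
#' instrument measurements.
#'
#' @param doubling_time_min Doubling time Td (default 25).
#' @param lag_min Lag before exponential growth (default 60).
#' @param carrying_capacity_od OD contributed by a saturated culture
#'   (default 1).
#' @param od_per_cell OD units per cell in a well (default 3e-8, making
#'   ~1e7 cells read ~0.3 above background).
#' @param background_od Medium background OD (default 0.1).
#' @param noise_cv Multiplicative noise CV (default 0 = noise-free).
#' @param interval_min Sampling interval (default 5).
#' @param duration_min Run length (default 1440, i.e. 24 h).
#' @param threshold_od Strain OD threshold carried as metadata (default 0.3).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(doubling_time_min = 25, lag_min = 60,
                       carrying_capacity_od = 1, od_per_cell = 3e-8,
                       background_od = 0.1, noise_cv = 0, interval_min = 5,
                       duration_min = 1440, threshold_od = 0.3) {
  stopifnot(doubling_time_min > 0, lag_min >= 0, carrying_capacity_od > 0,
            od_per_cell > 0, background_od >= 0, noise_cv >= 0,
            interval_min > 0, duration_min >= interval_min, threshold_od > 0)
  structure(list(doubling_time_min = doubling_time_min, lag_min = lag_min,
                 carrying_capacity_od = carrying_capacity_od,
                 od_per_cell = od_per_cell, background_od = background_od,
                 noise_cv = noise_cv, interval_min = interval_min,
                 duration_min = duration_min, threshold_od = threshold_od),
            class = "sim_params")
}

#' Synthetic strain presets
#'
#' Each preset carries the strain's published absolute OD threshold (0.3 for
#' the yeast- and E. coli-like presets, 0.15 for the lactobacillus-like
#' preset). The kinetic defaults (doubling times 90, 25 and 60 min; lag
#' 60 min) are synthetic test defaults, not measured values.
#'
#' @param name One of `"OP50-like"`, `"BY4742-like"`, `"LGG-like"`.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
strain_preset <- function(name = c("OP50-like", "BY4742-like", "LGG-like"),
                          ...) {
  name <- tryCatch(match.arg(name),
                   error = function(e) {
                     stop(sprintf(
                       "unknown preset '%s'; available presets: %s",
                       name[1],
                       paste(eval(formals(strain_preset)$name), collapse = ", ")),
                       call. = FALSE)
                   })
  base <- switch(name,
    "OP50-like" = list(doubling_time_min = 25, threshold_od = 0.3),
    "BY4742-like" = list(doubling_time_min = 90, threshold_od = 0.3),
    "LGG-like" = list(doubling_time_min = 60, threshold_od = 0.15))
  do.call(sim_params, utils::modifyList(c(base, lag_min = 60), list(...)))
}

#' Simulate one well
#'
#' @param params A [sim_params()].
#' @param n0 Initial cells in the well (>= 0; 0 gives flat background).
#' @param well_id Well label (default "A1").
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used, so that multi-well simulators draw independent noise per well).
#' @return A [well_series].
#' @export
simulate_well <- function(params, n0, well_id = "A1", seed = NULL) {
  stopifnot(inherits(params, "sim_params"), n0 >= 0)
  with_seed(seed, {
    tt <- seq(0, params$duration_min, by = params$interval_min)
    K <- params$carrying_capacity_od / params$od_per_cell
    mu <- log(2) / params$doubling_time_min
    n <- if (n0 <= 0) {
      rep(0, length(tt))
    } else {
      tg <- pmax(tt - params$lag_min, 0)
      K / (1 + (K / n0 - 1) * exp(-mu * tg))
    }
    od <- params$background_od + params$od_per_cell * n
    if (params$noise_cv > 0) {
      sdlog <- sqrt(log1p(params$noise_cv^2))
      od <- od * stats::rlnorm(length(od), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
    }
    well_series(well_id, tt, od)
  })
}

well_names_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Simulate a ten-fold dilution ladder on one plate
#'
#' Each well at exponent `e` is seeded with
#' `Poisson(stock * 10^e * inoculum_volume_uL / 1000)` cells and grown with
#' [simulate_well()]. Returns the run, the matching layout, and a truth
#' table for parameter-recovery tests. Deterministic under `seed`.
#'
#' @param params A [sim_params()].
#' @param stock_cfu_per_ml True stock concentration.
#' @param exponents Integer dilution exponents (<= 0), default `0:-7`.
#' @param replicates Wells per exponent (default 6).
#' @param inoculum_volume_uL Inoculum volume (default 5).
#' @param sample_id Sample label (default "S1").
#' @param seed Optional integer seed.
#' @return A list with `run` ([plate_run]), `layout` (`plate_layout`) and
#'   `truth` (data frame: `well`, `dilution_exponent`, `replicate`,
#'   `lambda`, `true_cells`, `stock_cfu_per_ml`).
#' @export
simulate_dilution_series <- function(params, stock_cfu_per_ml,
                                     exponents = 0:-7, replicates = 6,
                                     inoculum_volume_uL = 5,
                                     sample_id = "S1", seed = NULL) {
  stopifnot(inherits(params, "sim_params"), stock_cfu_per_ml > 0,
            all(exponents <= 0), replicates >= 1)
  nw <- length(exponents) * replicates
  if (nw > 96) stop("more than 96 wells requested", call. = FALSE)
  with_seed(seed, {
    ids <- well_names_96()[seq_len(nw)]
    grid <- expand.grid(replicate = seq_len(replicates),
                        dilution_exponent = exponents)
    grid <- grid[order(match(grid$dilution_exponent, exponents),
                       grid$replicate), ]
    lambda <- stock_cfu_per_ml * 10^grid$dilution_exponent *
      inoculum_volume_uL / 1000
    n0 <- stats::rpois(nw, lambda)
    wells <- lapply(seq_len(nw), function(i) {
      simulate_well(params, n0[i], well_id = ids[i])
    })
    layout <- as_plate_layout(data.frame(
      well = ids, sample_id = sample_id,
      dilution_exponent = grid$dilution_exponent,
      replicate = grid$replicate, role = "sample",
      inoculum_volume_uL = inoculum_volume_uL,
      stringsAsFactors = FALSE))
    truth <- data.frame(well = ids,
                        dilution_exponent = grid$dilution_exponent,
                        replicate = grid$replicate, lambda = lambda,
                        true_cells = n0,
                        stock_cfu_per_ml = stock_cfu_per_ml,
                        stringsAsFactors = FALSE)
    list(run = plate_run(wells, temperature_C = 30), layout = layout,
         truth = truth)
  })
}

#' Simulate a heat-treatment experiment (control vs treated wells)
#'
#' Control wells are Poisson-seeded from the stock. Treated wells draw the
#' same Poisson inoculum and then thin it binomially by `1 - kill_fraction`
#' (first-order thermal kill of individual cells); survivors grow with their
#' lag extended by `lag_extension_min` (sublethal injury).
#'
#' @param params A [sim_params()] describing the untreated strain.
#' @param stock_cfu_per_ml Stock concentration.
#' @param kill_fraction Fraction of cells killed, in `[0, 1]`.
#' @param lag_extension_min Additional lag of surviving cells (minutes).
#' @param replicates Wells per arm (default 6).
#' @param dilution_exponent Dilution applied to both arms (default 0).
#' @param inoculum_volume_uL Inoculum volume (default 5).
#' @param seed Optional integer seed.
#' @return A list with `run`, `layout` (sample ids `"control"`/`"treated"`)
#'   and `truth` (includes `cells_before_treatment` and `true_cells`).
#' @export
simulate_heat_treatment <- function(params, stock_cfu_per_ml, kill_fraction,
                                    lag_extension_min, replicates = 6,
                                    dilution_exponent = 0,
                                    inoculum_volume_uL = 5, seed = NULL) {
  stopifnot(inherits(params, "sim_params"),
            kill_fraction >= 0, kill_fraction <= 1, lag_extension_min >= 0)
  nw <- 2L * replicates
  if (nw > 96) stop("more than 96 wells requested", call. = FALSE)
  with_seed(seed, {
    ids <- well_names_96()[seq_len(nw)]
    lambda <- stock_cfu_per_ml * 10^dilution_exponent * inoculum_volume_uL / 1000
    n_ctrl <- stats::rpois(replicates, lambda)
    n_pre <- stats::rpois(replicates, lambda)
    n_trt <- stats::rbinom(replicates, n_pre, 1 - kill_fraction)
    p_trt <- params
    p_trt$lag_min <- params$lag_min + lag_extension_min
    wells <- c(
      lapply(seq_len(replicates), function(i) {
        simulate_well(params, n_ctrl[i], well_id = ids[i])
      }),
      lapply(seq_len(replicates), function(i) {
        simulate_well(p_trt, n_trt[i], well_id = ids[replicates + i])
      }))
    layout <- as_plate_layout(data.frame(
      well = ids,
      sample_id = rep(c("control", "treated"), each = replicates),
      dilution_exponent = dilution_exponent,
      replicate = rep(seq_len(replicates), 2L),
      role = "sample", inoculum_volume_uL = inoculum_volume_uL,
      stringsAsFactors = FALSE))
    truth <- data.frame(
      well = ids,
      sample_id = rep(c("control", "treated"), each = replicates),
      replicate = rep(seq_len(replicates), 2L),
      cells_before_treatment = c(n_ctrl, n_pre),
      true_cells = c(n_ctrl, n_trt),
      kill_fraction = rep(c(0, kill_fraction), each = replicates),
      lag_extension_min = rep(c(0, lag_extension_min), each = replicates),
      stringsAsFactors = FALSE)
    list(run = plate_run(wells, temperature_C = 30), layout = layout,
         truth = truth)
  })
}
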