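#' Kinetics fitting configuration
#'
#' Tunable parameters for per-well growth-curve analysis.
#'
#' @param window_w Sliding-window width (points) for the max-slope fit of
#'   log2 corrected OD; default 5 (25 min on a 5-min grid).
#' @param band Two fractions of the corrected OD maximum bounding the
#'   exponential-phase fitting band; default `c(0.01, 0.75)`. The lower edge
#'   excludes the region where baseline subtraction distorts log OD, the
#'   upper edge excludes the approach to saturation. The effective lower
#'   bound is the larger of `band[1] * max(corrected)` and
#'   `noise_mult * sd(first baseline_n raw readings)`.
#' @param baseline_n Number of initial readings used for the baseline median
#'   and the noise estimate; default 3.
#' @param floor Corrected-OD floor keeping logs finite; default 1e-4 OD.
#' @param noise_mult Multiplier on the baseline noise SD for the band's lower
#'   edge; default 3.
#' @param median_filter If `TRUE`, apply a 3-point running median to the OD
#'   trace before any analysis (off by default to preserve bit-exact
#'   reproducibility on clean data; recommended for noisy runs).
#' @param background Optional known background OD (e.g. the median of blank
#'   wells). When supplied it replaces the per-well self-baseline, which
#'   makes the initial biomass signal resolvable and the tangent lag
#'   identifiable; see the methods vignette.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(window_w = 5L, band = c(0.01, 0.75), baseline_n = 3L,
                       floor = 1e-4, noise_mult = 3, median_filter = FALSE,
                       background = NULL) {
  stopifnot(window_w >= 3L, length(band) == 2L, band[1] >= 0,
            band[2] > band[1], baseline_n >= 1L, floor > 0, noise_mult >= 0)
  structure(list(window_w = as.integer(window_w), band = band,
                 baseline_n = as.integer(baseline_n), floor = floor,
                 noise_mult = noise_mult, median_filter = isTRUE(median_filter),
                 background = background),
            class = "fit_config")
}

#' Load a kinetics configuration from a JSON file
#'
#' Keys mirror the arguments of [fit_config()]; additionally
#' `threshold_od` entries keyed by strain preset may be supplied and are
#' returned in the `thresholds` attribute.
#'
#' @param path Path to a JSON file.
#' @return A `fit_config` object.
#' @export
read_fit_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- intersect(names(raw), names(formals(fit_config)))
  cfg <- do.call(fit_config, raw[known])
  if (!is.null(raw$threshold_od)) attr(cfg, "thresholds") <- unlist(raw$threshold_od)
  cfg
}

#' Baseline-correct an OD series
#'
#' The baseline is the median of the first `n_initial` readings (or the
#' supplied known `background`); corrected OD is `max(od - baseline, floor)`.
#' The input series is not modified.
#'
#' @param series A [well_series].
#' @param n_initial Readings used for the baseline median (>= 1, < length).
#' @param floor Corrected-OD floor (default 1e-4).
#' @param background Optional known background OD overriding the self-baseline.
#' @return A list with `series` (corrected [well_series]) and `baseline_od`.
#' @export
baseline_correct <- function(series, n_initial = 3L, floor = 1e-4,
                             background = NULL) {
  stopifnot(inherits(series, "well_series"))
  n <- length(series$od)
  if (n_initial < 1L || n_initial >= n) {
    stop(sprintf("n_initial must be in [1, %d) for a %d-point series",
                 n, n), call. = FALSE)
  }
  baseline <- if (is.null(background)) {
    stats::median(series$od[seq_len(n_initial)])
  } else {
    as.numeric(background)
  }
  corrected <- pmax(series$od - baseline, floor)
  list(series = well_series(series$well_id, series$times, corrected),
       baseline_od = baseline)
}

#' Time to reach an absolute OD threshold
#'
#' First time the raw OD reaches the strain's threshold (0.3, or 0.15 for
#' slower-turbidity strains), with linear interpolation between the two
#' bracketing samples. The thresholds are absolute instrument readings, so
#' the comparison uses uncorrected OD.
#'
#' @param series A [well_series] (raw OD).
#' @param threshold_od Positive OD threshold.
#' @return Minutes to crossing; `0` if the first reading is already at or
#'   above threshold; `NA` if the threshold is never reached (censored).
#' @export
threshold_crossing <- function(series, threshold_od) {
  stopifnot(inherits(series, "well_series"), threshold_od > 0)
  od <- series$od
  tt <- series$times
  if (od[1] >= threshold_od) return(0)
  hit <- which(od >= threshold_od)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1]
  t0 <- tt[i - 1]; t1 <- tt[i]
  y0 <- od[i - 1]; y1 <- od[i]
  t0 + (threshold_od - y0) / (y1 - y0) * (t1 - t0)
}

# Max-slope sliding-window fit on log2 corrected OD. Returns NULL when no
# window of w in-band points exists (the no-growth signal).
max_slope_window <- function(series, config) {
  bc <- baseline_correct(series, config$baseline_n, config$floor,
                         config$background)
  x <- bc$series$od
  tt <- series$times
  nb <- min(config$baseline_n, length(series$od) - 1L)
  noise_sd <- if (nb >= 2L) stats::sd(series$od[seq_len(nb)]) else 0
  od_max <- max(x)
  lo <- max(config$noise_mult * noise_sd, config$band[1] * od_max)
  hi <- config$band[2] * od_max
  in_band <- x > config$floor & x >= lo & x <= hi
  w <- config$window_w
  n <- length(x)
  if (n < w) return(NULL)
  ok_start <- which(vapply(seq_len(n - w + 1L),
                           function(i) all(in_band[i:(i + w - 1L)]),
                           logical(1)))
  if (length(ok_start) == 0L) return(NULL)
  y <- log2(x)
  best <- NULL
  for (i in ok_start) {
    idx <- i:(i + w - 1L)
    ts <- tt[idx]; ys <- y[idx]
    vt <- stats::var(ts)
    slope <- stats::cov(ts, ys) / vt
    if (is.null(best) || slope > best$slope) {
      vy <- stats::var(ys)
      r2 <- if (vy > 0) stats::cov(ts, ys)^2 / (vt * vy) else 1
      best <- list(slope = slope, window = idx, r_squared = r2,
                   center_index = idx[ceiling(w / 2)])
    }
  }
  best$baseline_od <- bc$baseline_od
  best$corrected <- x
  best$od_max_corrected <- od_max
  best
}

#' Doubling time from the steepest log-linear window
#'
#' Fits least-squares lines to log2 baseline-corrected OD over a sliding
#' window restricted to the exponential-phase band and takes the steepest
#' slope; the doubling time is its reciprocal. Ties are broken toward the
#' earliest window.
#'
#' @param series A [well_series] (raw OD).
#' @param config A [fit_config()].
#' @return A list with `doubling_time_min`, `max_slope_log2_per_min`,
#'   `window` (indices of the winning window), `r_squared`, `baseline_od`,
#'   and `no_growth` (`TRUE` when no in-band window exists or the best slope
#'   is non-positive; the other fields are then `NA`).
#' @export
doubling_time <- function(series, config = fit_config()) {
  if (config$median_filter) {
    series <- well_series(series$well_id, series$times,
                          as.numeric(stats::runmed(series$od, 3L,
                                                   endrule = "median")))
  }
  best <- max_slope_window(series, config)
  if (is.null(best) || best$slope <= 0) {
    return(list(doubling_time_min = NA_real_,
                max_slope_log2_per_min = NA_real_,
                window = integer(0), r_squared = NA_real_,
                baseline_od = if (is.null(best)) NA_real_ else best$baseline_od,
                no_growth = TRUE))
  }
  list(doubling_time_min = 1 / best$slope,
       max_slope_log2_per_min = best$slope,
       window = best$window,
       r_squared = best$r_squared,
       baseline_od = best$baseline_od,
       center_index = best$center_index,
       corrected = best$corrected,
       no_growth = FALSE)
}

#' Tangent-intersection lag time
#'
#' Extends the steepest log2-linear tangent from the winning window's centre
#' back to the corrected OD of the first sample and reports the intersection
#' time, clamped to be non-negative. When the baseline is estimated from the
#' well's own first readings the initial biomass signal sits at the log
#' floor, and the reported lag absorbs an offset of
#' `Td * log2(floor / initial signal)`; supply a known `background` in the
#' configuration (e.g. from blank wells) to make the lag identifiable. The
#' threshold-crossing time is the more robust observable either way.
#'
#' @param series A [well_series] (raw OD).
#' @param dt_fit Result of [doubling_time()] on the same series and config.
#' @param config The same [fit_config()] used for `dt_fit`.
#' @return Lag in minutes (>= 0), or `NA` if `dt_fit` flagged no growth.
#' @export
lag_time <- function(series, dt_fit, config = fit_config()) {
  if (isTRUE(dt_fit$no_growth)) return(NA_real_)
  x <- dt_fit$corrected
  ic <- dt_fit$center_index
  t_w <- series$times[ic]
  s <- dt_fit$max_slope_log2_per_min
  lag <- t_w - (log2(x[ic]) - log2(x[1])) / s
  max(lag, 0)
}

#' Initial-biomass ratio inferred from crossing times
#'
#' Under pure exponential growth with shared kinetics, each missing doubling
#' of inoculum delays the threshold crossing by one doubling time, so the
#' initial-biomass ratio of two wells is
#' `2^(-(crossing - crossing_ref) / Td_ref)`.
#'
#' @param fit,reference [fit_growth()] results with uncensored crossings.
#' @return Dimensionless biomass ratio (fit relative to reference). A warning
#'   is issued when the two doubling times differ by more than 20%.
#' @export
relative_biomass <- function(fit, reference) {
  if (isTRUE(fit$censored) || isTRUE(reference$censored)) {
    stop("undefined biomass ratio: censored threshold crossing", call. = FALSE)
  }
  td <- reference$doubling_time_min
  if (!is.finite(td) || td <= 0) {
    stop("reference doubling time unavailable", call. = FALSE)
  }
  if (is.finite(fit$doubling_time_min) &&
      abs(fit$doubling_time_min - td) / td > 0.2) {
    warning("doubling times differ by more than 20%; ratio assumes shared kinetics",
            call. = FALSE)
  }
  2^(-(fit$crossing_min - reference$crossing_min) / td)
}

#' Fit all growth parameters for one well
#'
#' Composes baseline correction, the max-slope doubling-time fit, the tangent
#' lag and the absolute-threshold crossing into one `growth_fit`.
#' Deterministic given the series and configuration.
#'
#' @param series A [well_series] (raw OD).
#' @param threshold_od Absolute OD threshold (default 0.3; 0.15 for
#'   slow-turbidity strains such as lactobacilli).
#' @param config A [fit_config()].
#' @return An object of class `growth_fit` with fields `well_id`,
#'   `baseline_od`, `crossing_min`, `censored`, `saturated` (crossed at
#'   t = 0, doubling time unreliable), `no_growth`, `doubling_time_min`,
#'   `max_slope_log2_per_min`, `lag_min`, `od_max`, `threshold_od`,
#'   `window`, `r_squared`, `duration_min`.
#' @export
fit_growth <- function(series, threshold_od = 0.3, config = fit_config()) {
  stopifnot(inherits(series, "well_series"))
  work <- series
  if (config$median_filter) {
    work <- well_series(series$well_id, series$times,
                        as.numeric(stats::runmed(series$od, 3L,
                                                 endrule = "median")))
  }
  cfg_nf <- config
  cfg_nf$median_filter <- FALSE  # already applied
  dt <- doubling_time(work, cfg_nf)
  lag <- lag_time(work, dt, cfg_nf)
  crossing <- threshold_crossing(work, threshold_od)
  structure(list(
    well_id = series$well_id,
    baseline_od = dt$baseline_od,
    crossing_min = crossing,
    censored = is.na(crossing),
    saturated = !is.na(crossing) && crossing == 0,
    no_growth = dt$no_growth,
    doubling_time_min = dt$doubling_time_min,
    max_slope_log2_per_min = dt$max_slope_log2_per_min,
    lag_min = lag,
    od_max = max(work$od),
    threshold_od = threshold_od,
    window = dt$window,
    r_squared = dt$r_squared,
    duration_min = max(series$times)
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cross <- if (x$censored) "censored" else sprintf("%.1f min", x$crossing_min)
  td <- if (x$no_growth) "no growth" else sprintf("%.1f min", x$doubling_time_min)
  cat(sprintf("<growth_fit %s: crossing %s @ OD %.2f, Td %s, lag %s>\n",
              x$well_id, cross, x$threshold_od, td,
              if (is.na(x$lag_min)) "NA" else sprintf("%.1f min", x$lag_min)))
  invisible(x)
}

strain_thresholds <- c("BY4742-like" = 0.3, "OP50-like" = 0.3,
                       "LGG-like" = 0.15)

#' Fit growth parameters for every well of a run
#'
#' Thresholds are resolved per well: an explicit `threshold_od` wins,
#' otherwise the layout's `strain_preset` column ("BY4742-like"/"OP50-like"
#' give 0.3, "LGG-like" gives 0.15), otherwise 0.3.
#'
#' @param run A [plate_run].
#' @param layout Optional `plate_layout`.
#' @param threshold_od Optional single threshold overriding presets.
#' @param config A [fit_config()].
#' @return A named list of `growth_fit` objects (class `growth_fit_list`).
#' @export
fit_plate <- function(run, layout = NULL, threshold_od = NULL,
                      config = fit_config()) {
  stopifnot(inherits(run, "plate_run"))
  thr_for <- function(well) {
    if (!is.null(threshold_od)) return(threshold_od)
    if (!is.null(layout)) {
      p <- layout$strain_preset[layout$well == well]
      if (length(p) == 1L && !is.na(p) && p %in% names(strain_thresholds)) {
        return(unname(strain_thresholds[p]))
      }
    }
    0.3
  }
  fits <- lapply(run$wells, function(w) fit_growth(w, thr_for(w$well_id), config))
  structure(fits, class = "growth_fit_list")
}

#' Tabulate a list of growth fits
#'
#' @param x A `growth_fit_list` from [fit_plate()].
#' @param ... Unused.
#' @return One row per well with the scalar `growth_fit` fields.
#' @export
as.data.frame.growth_fit_list <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(f) {
    data.frame(well = f$well_id, baseline_od = f$baseline_od,
               crossing_min = f$crossing_min, censored = f$censored,
               saturated = f$saturated, no_growth = f$no_growth,
               doubling_time_min = f$doubling_time_min,
               max_slope_log2_per_min = f$max_slope_log2_per_min,
               lag_min = f$lag_min, od_max = f$od_max,
               threshold_od = f$threshold_od, r_squared = f$r_squared,
               stringsAsFactors = FALSE)
  }))
}
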