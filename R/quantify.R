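geomean <- function(x) exp(mean(log(x)))

#' Relative survival from a threshold-crossing delay
#'
#' The viable fraction of a well relative to a reference well:
#' `Vn = 2^(-(crossing - crossing_ref) / Td_ref)`, the inferred inoculum
#' ratio under shared exponential kinetics. The reference's doubling time is
#' used throughout; per-well doubling-time differences are diagnostics, not
#' part of `Vn`. Values above 1 (sample denser than reference) are allowed
#' but flagged. A censored sample crossing yields a below-detection upper
#' bound `2^(-(duration - crossing_ref) / Td_ref)` instead of a value.
#'
#' @param fit,reference `growth_fit` objects; the reference crossing must be
#'   uncensored and its doubling time defined.
#' @return A list with `survival`, `below_detection`, `upper_bound`,
#'   `flagged` (survival > 1).
#' @export
relative_survival <- function(fit, reference) {
  if (isTRUE(reference$censored)) {
    stop("reference crossing is censored; survival undefined", call. = FALSE)
  }
  td <- reference$doubling_time_min
  if (!is.finite(td) || td <= 0) {
    stop("reference doubling time unavailable", call. = FALSE)
  }
  if (isTRUE(fit$censored)) {
    ub <- 2^(-(fit$duration_min - reference$crossing_min) / td)
    return(list(survival = NA_real_, below_detection = TRUE,
                upper_bound = ub, flagged = FALSE))
  }
  v <- 2^(-(fit$crossing_min - reference$crossing_min) / td)
  list(survival = v, below_detection = FALSE, upper_bound = NA_real_,
       flagged = v > 1)
}

#' Per-dilution survival across a ladder
#'
#' Groups the sample wells of a layout by dilution exponent, picks the
#' provisional reference (the least-diluted exponent at which every
#' replicate crossed the threshold strictly after t = 0, so that its
#' doubling-time fit is trustworthy), and computes per-exponent survival as
#' the geometric mean over detected replicates of
#' `2^(-(crossing - mean reference crossing) / mean reference Td)`.
#' Survival is multiplicative, hence the geometric mean.
#'
#' @param fits A `growth_fit_list` from [fit_plate()].
#' @param layout A `plate_layout`.
#' @param sample_id Optional sample to restrict to.
#' @return A data frame of class `dilution_points` with columns `exponent`,
#'   `survival` (`NA` for non-detect points, which are retained), `n_detected`,
#'   `n_saturated` (wells already at threshold at t = 0, whose survival is
#'   only a lower bound), `n_total`, `flagged`; attributes
#'   `reference_exponent` (provisional),
#'   `reference_crossing_min`, `reference_td_min`.
#' @export
build_dilution_points <- function(fits, layout, sample_id = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  lay <- layout[layout$role == "sample" & !is.na(layout$dilution_exponent), ,
                drop = FALSE]
  if (!is.null(sample_id)) lay <- lay[lay$sample_id == sample_id, , drop = FALSE]
  if (nrow(lay) == 0L) stop("no sample wells in layout", call. = FALSE)
  missing <- setdiff(lay$well, names(fits))
  if (length(missing)) {
    stop(sprintf("no fits for layout well(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  exps <- sort(unique(lay$dilution_exponent), decreasing = TRUE)
  groups <- lapply(exps, function(e) fits[lay$well[lay$dilution_exponent == e]])

  usable_ref <- vapply(groups, function(g) {
    all(vapply(g, function(f) {
      !f$censored && f$crossing_min > 0 && !f$no_growth &&
        is.finite(f$doubling_time_min)
    }, logical(1)))
  }, logical(1))
  if (!any(usable_ref)) {
    stop("no usable reference dilution: every exponent has censored or saturated replicates",
         call. = FALSE)
  }
  ref_e <- exps[which(usable_ref)[1]]
  ref_fits <- groups[[which(usable_ref)[1]]]
  ref_cross <- mean(vapply(ref_fits, function(f) f$crossing_min, numeric(1)))
  # Doubling time comes from the most-diluted fully-detected exponent: its
  # wells carry the smallest inocula, so baseline subtraction distorts their
  # log-OD the least (see the methods vignette on Td estimation bias).
  td_fits <- groups[[max(which(usable_ref))]]
  ref_td <- mean(vapply(td_fits, function(f) f$doubling_time_min, numeric(1)))

  rows <- mapply(function(e, g) {
    cross <- vapply(g, function(f) f$crossing_min, numeric(1))
    det <- !is.na(cross)
    v <- if (any(det)) {
      geomean(2^(-(cross[det] - ref_cross) / ref_td))
    } else NA_real_
    data.frame(exponent = e, survival = v, n_detected = sum(det),
               n_saturated = sum(det & cross == 0),
               n_total = length(g),
               flagged = !is.na(v) && v > 1 + 1e-9)
  }, exps, groups, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "reference_exponent") <- ref_e
  attr(out, "reference_crossing_min") <- ref_cross
  attr(out, "reference_td_min") <- ref_td
  class(out) <- c("dilution_points", "data.frame")
  out
}

# Least-squares slope/intercept/r of log10(survival) on exponent. A run with
# zero variance in log survival (perfectly flat ladder) has slope 0 and an
# undefined correlation, reported as r = 0 so it never qualifies.
run_stats <- function(e, v) {
  y <- log10(v)
  slope <- stats::cov(e, y) / stats::var(e)
  intercept <- mean(y) - slope * mean(e)
  r <- if (stats::var(y) == 0) 0 else stats::cor(e, y)
  list(slope = slope, intercept = intercept, r = r, r_squared = r^2)
}

#' Find the calibrated linear range of a dilution ladder
#'
#' Enumerates every contiguous run of three or more consecutive exponents
#' with defined survival and accepts those whose least-squares regression of
#' log10 survival on dilution exponent has slope within `1 +/- slope_tol`
#' and R^2 at least `r2_min` (one lost decade of viable cells per ten-fold
#' dilution). The longest qualifying run wins; ties go to the run containing
#' the less-diluted points. Survival is renormalised so the accepted
#' reference (the run's least-diluted member, defined as 100% viability)
#' equals 1, and the regression statistics are recomputed on the accepted run.
#'
#' @param points A `dilution_points` data frame from [build_dilution_points()].
#' @param slope_tol Slope tolerance around 1 (default 0.1).
#' @param r2_min Minimum R^2 (default 0.99).
#' @return An object of class `calibration`: `reference_exponent`,
#'   `linear_range` (least-diluted, most-diluted), `slope`, `intercept`, `r`,
#'   `r_squared`, `points` (with `survival` renormalised to the accepted
#'   reference and an `in_linear_range` flag).
#'   On failure, an error of class `platecount_calibration_error` carrying a
#'   `diagnostics` data frame of every candidate run.
#' @export
find_linear_range <- function(points, slope_tol = 0.1, r2_min = 0.99) {
  pts <- points[is.finite(points$survival) & points$survival > 0, , drop = FALSE]
  # Survival computed from wells already at threshold when the run started
  # (crossing = 0) is only a lower bound on the delay; such points cannot
  # anchor the calibration.
  if (!is.null(pts$n_saturated)) {
    pts <- pts[pts$n_saturated == 0, , drop = FALSE]
  }
  pts <- pts[order(pts$exponent, decreasing = TRUE), , drop = FALSE]
  if (nrow(pts) < 3L) {
    stop("need at least 3 dilution points with defined survival", call. = FALSE)
  }
  cand <- list()
  n <- nrow(pts)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      e <- pts$exponent[i:j]
      if (!all(diff(e) == -1)) next
      st <- run_stats(e, pts$survival[i:j])
      cand[[length(cand) + 1L]] <- data.frame(
        from = e[1], to = e[length(e)], length = length(e),
        slope = st$slope, r_squared = st$r_squared,
        ok = abs(st$slope - 1) <= slope_tol && st$r_squared >= r2_min)
    }
  }
  if (length(cand) == 0L) {
    stop(errorCondition("no contiguous run of >= 3 consecutive exponents",
                        class = "platecount_calibration_error"))
  }
  diag <- do.call(rbind, cand)
  ok <- diag[diag$ok, , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop(errorCondition(
      paste0("no run of >= 3 consecutive dilutions satisfies ",
             sprintf("slope in 1 +/- %g and R^2 >= %g", slope_tol, r2_min)),
      class = "platecount_calibration_error", diagnostics = diag))
  }
  ok <- ok[order(-ok$length, -ok$from), , drop = FALSE]
  best <- ok[1, ]
  sel <- points$exponent <= best$from & points$exponent >= best$to
  ref_e <- best$from
  v_ref <- points$survival[points$exponent == ref_e]
  out_pts <- points
  out_pts$survival <- out_pts$survival / v_ref
  out_pts$in_linear_range <- sel
  st <- run_stats(out_pts$exponent[sel & is.finite(out_pts$survival)],
                  out_pts$survival[sel & is.finite(out_pts$survival)])
  structure(list(
    reference_exponent = ref_e,
    linear_range = c(best$from, best$to),
    slope = st$slope, intercept = st$intercept,
    r = st$r, r_squared = st$r_squared,
    points = as.data.frame(out_pts),
    provisional_reference = attr(points, "reference_exponent"),
    reference_td_min = attr(points, "reference_td_min"),
    diagnostics = diag
  ), class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration: linear range 10^%d..10^%d (%d decades), slope %.3f, r %.4f>\n",
    x$linear_range[1], x$linear_range[2], dynamic_range(x), x$slope, x$r))
  invisible(x)
}

#' Width of the calibrated linear range, in decades
#'
#' @param calibration A `calibration` from [find_linear_range()].
#' @return Integer count of ten-fold dilutions in the range, inclusive.
#' @export
dynamic_range <- function(calibration) {
  as.integer(calibration$linear_range[1] - calibration$linear_range[2] + 1)
}

#' Absolute concentration from the anchored survival
#'
#' `Q = N_min * Vn * (1000 / inoculum volume)`: the spread-plate count at the
#' minimal dilution in the linear range (CFU per inoculum) times the relative
#' survival, converted to CFU/mL. With the standard 5 uL inoculum the
#' conversion factor is exactly 200.
#'
#' @param n_min CFU per inoculum volume at the reference (minimal) dilution,
#'   from one spread-plate count.
#' @param vn Relative survival of the sample versus the reference dilution.
#' @param inoculum_volume_uL Inoculum volume per well (default 5).
#' @return CFU/mL.
#' @export
cfu_per_ml <- function(n_min, vn, inoculum_volume_uL = 5) {
  if (!is.finite(n_min) || n_min <= 0) stop("n_min must be > 0", call. = FALSE)
  if (!is.finite(vn) || vn <= 0) stop("vn must be > 0", call. = FALSE)
  if (!is.finite(inoculum_volume_uL) || inoculum_volume_uL <= 0) {
    stop("inoculum_volume_uL must be > 0", call. = FALSE)
  }
  n_min * vn * (1000 / inoculum_volume_uL)
}

#' Correlation between measured and dilution-predicted counts
#'
#' Pearson correlation of log10 actual CFU against log10 diluted-ratio CFU.
#' The log-log scale is used because decade-spaced data on a linear scale
#' degenerate to leverage by the least-diluted point.
#'
#' @param actual,expected Positive vectors of equal length (>= 3).
#' @return Pearson r.
#' @export
correlate_actual_vs_expected <- function(actual, expected) {
  if (length(actual) != length(expected) || length(actual) < 3L) {
    stop("need at least 3 paired values", call. = FALSE)
  }
  if (any(actual <= 0) || any(expected <= 0)) {
    stop("counts must be positive for log10 correlation", call. = FALSE)
  }
  stats::cor(log10(actual), log10(expected))
}

#' Quantify a sample from a plate run: ladder, calibration, CFU/mL
#'
#' The full quantification pipeline: per-well kinetics, per-dilution
#' survival, linear-range calibration, and the absolute count
#' `Q = N_min * Vn * (1000/V)`. The reported `q_cfu_per_ml` is the undiluted
#' sample's concentration obtained by the decade law inside the accepted
#' range, `N_min * 10^(-reference exponent) * (1000/V)`. When the
#' spread-plate anchor was counted at a dilution other than the reference,
#' pass `n_min_exponent` and the anchor is rescaled through the measured
#' survival ratio.
#'
#' @param run A [plate_run].
#' @param layout A `plate_layout`.
#' @param n_min Spread-plate count (CFU per inoculum volume) at
#'   `n_min_exponent`.
#' @param n_min_exponent Dilution exponent at which `n_min` was counted;
#'   `NULL` (default) means the reference dilution itself.
#' @param sample_id Optional sample restriction.
#' @param threshold_od Optional threshold override (see [fit_plate()]).
#' @param config A [fit_config()].
#' @param slope_tol,r2_min Linear-range acceptance, see [find_linear_range()].
#' @return An object of class `quant_result`.
#' @export
quantify_run <- function(run, layout, n_min, n_min_exponent = NULL,
                         sample_id = NULL, threshold_od = NULL,
                         config = fit_config(), slope_tol = 0.1,
                         r2_min = 0.99) {
  fits <- fit_plate(run, layout, threshold_od, config)
  pts <- build_dilution_points(fits, layout, sample_id)
  cal <- find_linear_range(pts, slope_tol, r2_min)
  sel <- layout$role == "sample" & !is.na(layout$dilution_exponent)
  if (!is.null(sample_id)) sel <- sel & layout$sample_id == sample_id
  vol <- unique(layout$inoculum_volume_uL[sel])
  if (length(vol) != 1L) {
    stop("sample wells must share one inoculum volume", call. = FALSE)
  }
  n_min_ref <- n_min
  if (!is.null(n_min_exponent) && n_min_exponent != cal$reference_exponent) {
    v_at <- cal$points$survival[cal$points$exponent == n_min_exponent]
    if (length(v_at) != 1L || !is.finite(v_at) || v_at <= 0) {
      stop(sprintf("no measured survival at anchor exponent %d", n_min_exponent),
           call. = FALSE)
    }
    n_min_ref <- n_min / v_at
  }
  q <- cfu_per_ml(n_min_ref, 10^(-cal$reference_exponent), vol)
  structure(list(
    sample_id = if (is.null(sample_id)) unique(layout$sample_id[sel]) else sample_id,
    reference_exponent = cal$reference_exponent,
    linear_range = cal$linear_range,
    slope = cal$slope, intercept = cal$intercept, r = cal$r,
    r_squared = cal$r_squared,
    n_min = n_min_ref,
    inoculum_volume_uL = vol,
    q_cfu_per_ml = q,
    dynamic_range_decades = dynamic_range(cal),
    per_dilution = cal$points,
    reference_td_min = cal$reference_td_min
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result %s>\n", paste(x$sample_id, collapse = ",")))
  cat(sprintf("  linear range : 10^%d .. 10^%d (%d decades)\n",
              x$linear_range[1], x$linear_range[2], x$dynamic_range_decades))
  cat(sprintf("  slope %.3f, r %.4f\n", x$slope, x$r))
  cat(sprintf("  N_min (10^%d) : %.4g CFU / %g uL\n", x$reference_exponent,
              x$n_min, x$inoculum_volume_uL))
  cat(sprintf("  Q             : %.4g CFU/mL\n", x$q_cfu_per_ml))
  invisible(x)
}

#' Write a quantification result as JSON
#'
#' @param result A `quant_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_json <- function(result, path) {
  stopifnot(inherits(result, "quant_result"))
  doc <- list(
    sample_id = result$sample_id,
    reference_exponent = result$reference_exponent,
    linear_range = result$linear_range,
    slope = result$slope, intercept = result$intercept, r = result$r,
    n_min = result$n_min,
    inoculum_volume_uL = result$inoculum_volume_uL,
    q_cfu_per_ml = result$q_cfu_per_ml,
    dynamic_range_decades = result$dynamic_range_decades,
    per_dilution = result$per_dilution
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
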