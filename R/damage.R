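#' Compare a heat-treated well against its untreated control
#'
#' Quantifies thermal injury from paired growth curves: the crossing-based
#' relative survival ([relative_survival()]), the shifts in threshold
#' crossing and tangent lag (treated minus control), and a three-state
#' classification. Because a pure kill and a pure lag extension both delay
#' the crossing, the crossing-based survival confounds the two when injury
#' extends the survivors' lag; `survival_lag_adjusted`
#' (`2^(-(crossing_shift - lag_shift) / Td_control)`) separates them, but is
#' only meaningful when the tangent lag itself is identifiable (fits made
#' with a known background; see [lag_time()] and the methods vignette).
#'
#' @param treated,control `growth_fit` objects; the control must be
#'   uncensored.
#' @param s_lo Survival below which a culturable well is called damaged
#'   (default 0.5).
#' @param lag_delta_min Lag extension beyond which a well is called damaged
#'   (default 10 min, two 5-min sampling intervals).
#' @param temperature_C,minutes Optional treatment metadata, echoed back.
#' @return An object of class `treatment_comparison` with fields `survival`,
#'   `survival_lag_adjusted`, `upper_bound` (when the treated well never
#'   grew), `crossing_shift_min`, `lag_shift_min`, `state`, `thresholds`,
#'   `temperature_C`, `minutes`.
#' @export
compare_treated <- function(treated, control, s_lo = 0.5, lag_delta_min = 10,
                            temperature_C = NA_real_, minutes = NA_real_) {
  if (isTRUE(control$censored)) {
    stop("control crossing is censored; cannot serve as reference",
         call. = FALSE)
  }
  rs <- relative_survival(treated, control)
  crossing_shift <- if (treated$censored) NA_real_ else
    treated$crossing_min - control$crossing_min
  lag_shift <- if (is.na(treated$lag_min) || is.na(control$lag_min)) NA_real_
    else treated$lag_min - control$lag_min
  adj <- if (!is.na(crossing_shift) && !is.na(lag_shift)) {
    2^(-(crossing_shift - lag_shift) / control$doubling_time_min)
  } else NA_real_
  cmp <- structure(list(
    survival = rs$survival,
    survival_lag_adjusted = adj,
    upper_bound = rs$upper_bound,
    crossing_shift_min = crossing_shift,
    lag_shift_min = lag_shift,
    treated_censored = isTRUE(treated$censored),
    thresholds = c(s_lo = s_lo, lag_delta_min = lag_delta_min),
    temperature_C = temperature_C, minutes = minutes
  ), class = "treatment_comparison")
  cmp$state <- classify_state(cmp, s_lo, lag_delta_min)
  cmp
}

#' Three-state viability call: normal / damaged / dead
#'
#' Dead when the treated well never reached the threshold within the run;
#' damaged when its crossing-based survival falls below `s_lo` or its lag is
#' extended by more than `lag_delta_min`; normal otherwise. The numeric
#' thresholds are this package's operational definitions (the underlying
#' observations are qualitative) and are echoed in every comparison.
#'
#' @param comparison A `treatment_comparison`.
#' @param s_lo,lag_delta_min See [compare_treated()].
#' @return `"normal"`, `"damaged"` or `"dead"`.
#' @export
classify_state <- function(comparison, s_lo = 0.5, lag_delta_min = 10) {
  if (isTRUE(comparison$treated_censored)) return("dead")
  damaged <- (is.finite(comparison$survival) && comparison$survival < s_lo) ||
    (is.finite(comparison$lag_shift_min) &&
       comparison$lag_shift_min > lag_delta_min)
  if (damaged) "damaged" else "normal"
}

#' @export
print.treatment_comparison <- function(x, ...) {
  surv <- if (is.na(x$survival)) {
    sprintf("< %.3g (below detection)", x$upper_bound)
  } else sprintf("%.3f", x$survival)
  cat(sprintf("<treatment_comparison: state %s, survival %s, crossing shift %s, lag shift %s>\n",
              x$state, surv,
              if (is.na(x$crossing_shift_min)) "NA" else
                sprintf("%+.1f min", x$crossing_shift_min),
              if (is.na(x$lag_shift_min)) "NA" else
                sprintf("%+.1f min", x$lag_shift_min)))
  invisible(x)
}

#' Treated-vs-control comparison across a whole plate
#'
#' Fits every well, averages the control wells into a pooled reference
#' (mean crossing, lag and doubling time over uncensored controls) and
#' compares each treated well against it.
#'
#' @param run A [plate_run].
#' @param layout A `plate_layout` whose `sample_id` distinguishes the arms.
#' @param control_sample,treated_sample Sample ids of the two arms.
#' @param threshold_od,config Passed to [fit_plate()].
#' @param s_lo,lag_delta_min Classification thresholds, see
#'   [compare_treated()].
#' @return A data frame, one row per treated well, with the comparison
#'   fields.
#' @export
compare_plate <- function(run, layout, control_sample = "control",
                          treated_sample = "treated", threshold_od = NULL,
                          config = fit_config(), s_lo = 0.5,
                          lag_delta_min = 10) {
  fits <- fit_plate(run, layout, threshold_od, config)
  ctrl_wells <- layout$well[layout$sample_id == control_sample]
  trt_wells <- layout$well[layout$sample_id == treated_sample]
  if (!length(ctrl_wells) || !length(trt_wells)) {
    stop("control or treated sample not found in layout", call. = FALSE)
  }
  ctrl <- fits[ctrl_wells]
  usable <- vapply(ctrl, function(f) !f$censored && !f$no_growth, logical(1))
  if (!any(usable)) stop("no usable control wells", call. = FALSE)
  pool <- list(
    well_id = "control-pool",
    crossing_min = mean(vapply(ctrl[usable], `[[`, numeric(1), "crossing_min")),
    censored = FALSE,
    doubling_time_min = mean(vapply(ctrl[usable], `[[`, numeric(1),
                                    "doubling_time_min")),
    lag_min = mean(vapply(ctrl[usable], `[[`, numeric(1), "lag_min")),
    duration_min = ctrl[[1]]$duration_min
  )
  class(pool) <- "growth_fit"
  rows <- lapply(trt_wells, function(w) {
    cmp <- compare_treated(fits[[w]], pool, s_lo, lag_delta_min)
    data.frame(well = w, survival = cmp$survival,
               survival_lag_adjusted = cmp$survival_lag_adjusted,
               upper_bound = cmp$upper_bound,
               crossing_shift_min = cmp$crossing_shift_min,
               lag_shift_min = cmp$lag_shift_min, state = cmp$state,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
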