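#' One well's optical-density time series
#'
#' The atomic data unit of a plate run: a single well's OD readings at 660 nm
#' on a common time grid, in minutes from the start of the run.
#'
#' @param well_id Plate coordinate, e.g. `"A1"`.
#' @param times Numeric vector of minutes from run start, strictly increasing.
#' @param od Numeric vector of OD readings, same length as `times`, finite
#'   and non-negative.
#' @return An object of class `well_series`: a list with elements `well_id`,
#'   `times` and `od`.
#' @examples
#' ws <- well_series("A1", c(0, 5, 10), c(0.09, 0.10, 0.12))
#' @export
well_series <- function(well_id, times, od) {
  if (!is.character(well_id) || length(well_id) != 1L || is.na(well_id)) {
    stop("`well_id` must be a single string", call. = FALSE)
  }
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) != length(od)) {
    stop(sprintf("well %s: times and od differ in length (%d vs %d)",
                 well_id, length(times), length(od)), call. = FALSE)
  }
  if (length(times) < 2L) {
    stop(sprintf("well %s: at least two readings required", well_id),
         call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(od))) {
    stop(sprintf("well %s: non-finite time or OD reading", well_id),
         call. = FALSE)
  }
  if (any(od < 0)) {
    stop(sprintf("well %s: negative OD reading", well_id), call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop(sprintf("well %s: times not strictly increasing", well_id),
         call. = FALSE)
  }
  structure(list(well_id = well_id, times = times, od = od),
            class = "well_series")
}

#' @export
print.well_series <- function(x, ...) {
  cat(sprintf("<well_series %s: %d readings, %g-%g min, OD %.3f-%.3f>\n",
              x$well_id, length(x$times), min(x$times), max(x$times),
              min(x$od), max(x$od)))
  invisible(x)
}

#' A full plate-reader run
#'
#' A collection of [well_series] objects sharing one exact time grid, with
#' acquisition metadata. Temperature and wavelength are retained as metadata
#' only; they do not enter any computation.
#'
#' @param wells A list of [well_series] objects with unique well ids.
#' @param wavelength_nm Acquisition wavelength (default 660).
#' @param temperature_C Incubation temperature, metadata only.
#' @return An object of class `plate_run` with elements `wells` (named list),
#'   `interval_minutes`, `duration_minutes`, `wavelength_nm`, `temperature_C`.
#' @export
plate_run <- function(wells, wavelength_nm = 660, temperature_C = NA_real_) {
  if (!is.list(wells) || length(wells) == 0L) {
    stop("`wells` must be a non-empty list of well_series", call. = FALSE)
  }
  ok <- vapply(wells, inherits, logical(1), what = "well_series")
  if (!all(ok)) stop("all elements of `wells` must be well_series", call. = FALSE)
  ids <- vapply(wells, function(w) w$well_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate well id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  names(wells) <- ids
  grid <- wells[[1]]$times
  same <- vapply(wells, function(w) identical(w$times, grid), logical(1))
  if (!all(same)) {
    stop(sprintf("well(s) %s not on the common time grid (ragged run)",
                 paste(ids[!same], collapse = ", ")), call. = FALSE)
  }
  structure(list(
    wells = wells,
    interval_minutes = stats::median(diff(grid)),
    duration_minutes = max(grid),
    wavelength_nm = wavelength_nm,
    temperature_C = temperature_C
  ), class = "plate_run")
}

#' @export
print.plate_run <- function(x, ...) {
  cat(sprintf(
    "<plate_run: %d wells, %d timepoints, %g min interval, %g min duration>\n",
    length(x$wells), length(x$wells[[1]]$times), x$interval_minutes,
    x$duration_minutes))
  invisible(x)
}

plate_roles <- c("sample", "blank", "reference")

#' Read a plate-reader run from CSV
#'
#' Accepts two dialects. Long (canonical): columns `well`, `time_min`, `od`,
#' one row per reading; rows may arrive in any order. Wide: a `time_min`
#' column plus one column per well. Both produce identical [plate_run]
#' structures. The sampling grid is taken exactly as found in the file; a
#' 5-minute grid is typical but not assumed.
#'
#' @param path Path to a CSV file.
#' @return A validated [plate_run].
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  long_cols <- c("well", "time_min", "od")
  if (all(long_cols %in% names(df))) {
    parse_long_run(df)
  } else if ("time_min" %in% names(df) && ncol(df) >= 2L) {
    parse_wide_run(df)
  } else {
    stop(paste0("unrecognized plate CSV format: need columns well,time_min,od ",
                "(long) or time_min plus one column per well (wide); found: ",
                paste(names(df), collapse = ", ")), call. = FALSE)
  }
}

parse_long_run <- function(df) {
  if (nrow(df) == 0L) stop("empty plate file", call. = FALSE)
  df$time_min <- as.numeric(df$time_min)
  df$od <- as.numeric(df$od)
  if (any(is.na(df$time_min)) || any(is.na(df$od))) {
    stop("non-numeric time_min or od value", call. = FALSE)
  }
  wells <- lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    if (anyDuplicated(d$time_min)) {
      stop(sprintf("well %s: duplicate (well, time_min) rows at t = %s",
                   d$well[1],
                   paste(unique(d$time_min[duplicated(d$time_min)]),
                         collapse = ", ")), call. = FALSE)
    }
    well_series(as.character(d$well[1]), d$time_min, d$od)
  })
  plate_run(wells)
}

parse_wide_run <- function(df) {
  if (nrow(df) == 0L) stop("empty plate file", call. = FALSE)
  times <- as.numeric(df$time_min)
  if (any(is.na(times))) stop("non-numeric time_min value", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("wide-format time_min column not strictly increasing", call. = FALSE)
  }
  well_cols <- setdiff(names(df), "time_min")
  wells <- lapply(well_cols, function(w) {
    od <- as.numeric(df[[w]])
    if (any(is.na(od))) {
      stop(sprintf("well %s: non-numeric od value", w), call. = FALSE)
    }
    well_series(w, times, od)
  })
  plate_run(wells)
}

#' Write a plate run as canonical long CSV
#'
#' Numbers are written with 17 significant digits so that a write/read
#' round trip reproduces times and OD values bit-identically.
#'
#' @param run A [plate_run].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(run, path) {
  stopifnot(inherits(run, "plate_run"))
  rows <- lapply(run$wells, function(w) {
    sprintf("%s,%.17g,%.17g", w$well_id, w$times, w$od)
  })
  writeLines(c("well,time_min,od", unlist(rows, use.names = FALSE)), path)
  invisible(path)
}

#' Read a plate layout table
#'
#' The layout maps wells to samples, ten-fold dilution exponents, replicates
#' and roles. Required columns: `well`, `sample_id`, `dilution_exponent`,
#' `replicate`, `role`. Optional: `strain_preset` (carries the strain's OD
#' threshold), `inoculum_volume_uL` (default 5). Roles are one of
#' `sample`, `blank`, `reference`; blank wells must carry no dilution
#' exponent.
#'
#' @param path Path to a layout CSV.
#' @return A `plate_layout` data frame.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty layout file", call. = FALSE)
  req <- c("well", "sample_id", "dilution_exponent", "replicate", "role")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("layout missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  as_plate_layout(df)
}

#' Construct/validate a plate layout from a data frame
#'
#' @param df Data frame with the columns documented in [read_layout()].
#' @return A `plate_layout` data frame.
#' @export
as_plate_layout <- function(df) {
  df$well <- as.character(df$well)
  if (anyDuplicated(df$well)) {
    stop(sprintf("well(s) referenced twice in layout: %s",
                 paste(unique(df$well[duplicated(df$well)]), collapse = ", ")),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(df$role), plate_roles)
  if (length(bad_role)) {
    stop(sprintf("unknown role(s) %s; allowed roles: %s",
                 paste(bad_role, collapse = ", "),
                 paste(plate_roles, collapse = ", ")), call. = FALSE)
  }
  df$dilution_exponent <- suppressWarnings(as.numeric(df$dilution_exponent))
  has_e <- !is.na(df$dilution_exponent)
  if (any(df$dilution_exponent[has_e] > 0)) {
    stop("dilution_exponent must be <= 0 (ten-fold dilutions of the sample)",
         call. = FALSE)
  }
  if (any(has_e & df$dilution_exponent != round(df$dilution_exponent))) {
    stop("dilution_exponent must be an integer", call. = FALSE)
  }
  if (any(df$role == "blank" & has_e)) {
    stop("blank wells must carry no dilution_exponent", call. = FALSE)
  }
  if (is.null(df$inoculum_volume_uL)) df$inoculum_volume_uL <- 5
  df$inoculum_volume_uL[is.na(df$inoculum_volume_uL)] <- 5
  if (any(df$inoculum_volume_uL <= 0)) {
    stop("inoculum_volume_uL must be > 0", call. = FALSE)
  }
  if (is.null(df$strain_preset)) df$strain_preset <- NA_character_
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' Cross-check a plate run against its layout
#'
#' Never fails: returns a data frame of findings. Wells present in the layout
#' but absent from the run are reported as `missing_data`; wells with data
#' but no layout entry as `not_in_layout` (informational). An empty result
#' means run and layout agree well-for-well.
#'
#' @param run A [plate_run].
#' @param layout A `plate_layout`.
#' @return Data frame with columns `well`, `status`, `message`.
#' @export
validate_run <- function(run, layout) {
  stopifnot(inherits(run, "plate_run"), inherits(layout, "plate_layout"))
  run_wells <- names(run$wells)
  lay_wells <- layout$well
  miss_data <- setdiff(lay_wells, run_wells)
  miss_lay <- setdiff(run_wells, lay_wells)
  findings <- data.frame(
    well = c(miss_data, miss_lay),
    status = c(rep("missing_data", length(miss_data)),
               rep("not_in_layout", length(miss_lay))),
    stringsAsFactors = FALSE
  )
  findings$message <- ifelse(
    findings$status == "missing_data",
    "well listed in layout but absent from the run",
    "well present in the run but not in the layout (informational)")
  findings[order(findings$well), , drop = FALSE]
}
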