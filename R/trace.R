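#' Occupancy probability for colonies scattered over a grid
#'
#' When `n_items` colonies land independently and uniformly among
#' `n_sectors` grid sectors (or wells), the count in any one sector is
#' Binomial(`n_items`, 1/`n_sectors`). The Poisson approximation with
#' `lambda = n_items / n_sectors` is reported alongside; the binomial is the
#' reference model because the total number of colonies is fixed.
#'
#' @param n_items Number of colonies placed (>= 0).
#' @param n_sectors Number of sectors (>= 1).
#' @param k Occupancy count of interest (>= 0; `k > n_items` gives 0).
#' @return A list with `binomial`, `poisson` and `lambda`.
#' @export
occupancy_fraction <- function(n_items, n_sectors, k) {
  if (n_sectors < 1) stop("n_sectors must be >= 1", call. = FALSE)
  if (n_items < 0 || k < 0) stop("n_items and k must be >= 0", call. = FALSE)
  list(binomial = stats::dbinom(k, n_items, 1 / n_sectors),
       poisson = stats::dpois(k, n_items / n_sectors),
       lambda = n_items / n_sectors)
}

#' Monte-Carlo occupancy distribution
#'
#' Repeatedly scatters `n_items` colonies uniformly over `n_sectors` sectors
#' and tabulates the empirical per-sector occupancy distribution.
#' Reproducible under a fixed seed; the caller's RNG state is preserved.
#'
#' @param n_items,n_sectors As in [occupancy_fraction()].
#' @param reps Number of simulated plates (>= 1).
#' @param seed Optional integer seed.
#' @return A named numeric vector: the empirical probability of occupancy
#'   `0 .. n_items` per sector.
#' @export
simulate_occupancy <- function(n_items, n_sectors, reps, seed = NULL) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (n_sectors < 1) stop("n_sectors must be >= 1", call. = FALSE)
  with_seed(seed, {
    if (n_items == 0) {
      pmf <- c(`0` = 1)
    } else {
      counts <- stats::rmultinom(reps, n_items, rep(1 / n_sectors, n_sectors))
      pmf <- tabulate(counts + 1L, nbins = n_items + 1L) /
        (as.numeric(n_sectors) * reps)
      names(pmf) <- 0:n_items
    }
    pmf
  })
}

#' Mean cells per well from the sterile fraction
#'
#' The single-tier limiting-dilution (most probable number) estimator: under
#' Poisson seeding the fraction of sterile (no-growth) wells is
#' `P(0) = exp(-lambda)`, so `lambda = -ln(p0)`.
#'
#' @param p0 Observed sterile fraction, strictly between 0 and 1.
#' @return Estimated mean cells per well.
#' @export
lambda_from_sterile_fraction <- function(p0) {
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) {
    stop(paste0("sterile fraction must be strictly between 0 and 1; ",
                "all-growth (p0 = 0) or no-growth (p0 = 1) plates carry no ",
                "information about lambda - change the dilution and re-plate"),
         call. = FALSE)
  }
  -log(p0)
}

#' Decades detectable from the reference-dilution well count
#'
#' Counts the consecutive ten-fold dilutions, starting at the reference, for
#' which the expected cells per well stay at or above one. This is the
#' count-limited floor of the dynamic range; strains whose doubling time is
#' too long to reach the OD threshold within the run are limited earlier by
#' time, which is handled by the linear-range calibration, not here.
#'
#' @param n_min_per_well Expected CFU per well at the reference dilution.
#' @param max_decades Cap on the answer (default 10).
#' @return Integer number of detectable decades (0 when `n_min_per_well < 1`).
#' @export
detectable_decades <- function(n_min_per_well, max_decades = 10L) {
  if (!is.finite(n_min_per_well) || n_min_per_well < 1) return(0L)
  as.integer(min(floor(log10(n_min_per_well) + 1e-9) + 1, max_decades))
}
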