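#' Consumable specification for an enumeration protocol
#'
#' @param name Protocol label.
#' @param samples Number of samples processed.
#' @param tips_per_sample Pipette tips per sample.
#' @param vessels_total Total culture vessels (dishes or microplates).
#' @param medium_uL_per_vessel Medium volume per vessel, in microlitres.
#' @param cost_per_tip,cost_per_vessel,cost_per_mL_medium Unit costs in any
#'   one currency; ratios are invariant to the unit.
#' @param cost_per_sample Optional measured per-sample consumable cost that
#'   overrides the unit-cost computation.
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(name, samples, tips_per_sample, vessels_total,
                          medium_uL_per_vessel, cost_per_tip = 0,
                          cost_per_vessel = 0, cost_per_mL_medium = 0,
                          cost_per_sample = NULL) {
  stopifnot(samples > 0, tips_per_sample >= 0, vessels_total >= 0,
            medium_uL_per_vessel >= 0, cost_per_tip >= 0,
            cost_per_vessel >= 0, cost_per_mL_medium >= 0)
  structure(list(name = name, samples = samples,
                 tips_per_sample = tips_per_sample,
                 vessels_total = vessels_total,
                 medium_uL_per_vessel = medium_uL_per_vessel,
                 cost_per_tip = cost_per_tip,
                 cost_per_vessel = cost_per_vessel,
                 cost_per_mL_medium = cost_per_mL_medium,
                 cost_per_sample = cost_per_sample),
            class = "protocol_spec")
}

#' Default spread-plate consumable spec
#'
#' Seven tips per sample and three plated dilutions per sample (so 288
#' dishes for a 96-sample batch) at 20 mL agar per dish - the per-dish
#' volume is an inferred default reproducing a 5760 mL total for 96 samples.
#'
#' @param samples Number of samples (default 96).
#' @param dilutions_plated Dishes per sample (default 3).
#' @param medium_mL_per_dish Agar per dish (default 20).
#' @param ... Passed to [protocol_spec()] (e.g. `cost_per_sample`).
#' @return A `protocol_spec`.
#' @export
spread_plate_protocol <- function(samples = 96, dilutions_plated = 3,
                                  medium_mL_per_dish = 20, ...) {
  protocol_spec("spread plate", samples, tips_per_sample = 7,
                vessels_total = samples * dilutions_plated,
                medium_uL_per_vessel = medium_mL_per_dish * 1000, ...)
}

#' Default microplate (high-throughput) consumable spec
#'
#' Two tips per sample and 100 uL of medium per well, one 96-well plate per
#' 96 samples (9.6 mL per full plate).
#'
#' @param samples Number of samples (default 96).
#' @param wells_per_plate Plate capacity (default 96).
#' @param medium_uL_per_well Medium per well (default 100).
#' @param ... Passed to [protocol_spec()].
#' @return A `protocol_spec`.
#' @export
microplate_protocol <- function(samples = 96, wells_per_plate = 96,
                                medium_uL_per_well = 100, ...) {
  protocol_spec("high-throughput", samples, tips_per_sample = 2,
                vessels_total = ceiling(samples / wells_per_plate),
                medium_uL_per_vessel = medium_uL_per_well *
                  min(samples, wells_per_plate), ...)
}

protocol_totals <- function(p) {
  tips <- p$tips_per_sample * p$samples
  medium_mL <- p$vessels_total * p$medium_uL_per_vessel / 1000
  cost_ps <- if (!is.null(p$cost_per_sample)) {
    p$cost_per_sample
  } else {
    (tips * p$cost_per_tip + p$vessels_total * p$cost_per_vessel +
       medium_mL * p$cost_per_mL_medium) / p$samples
  }
  c(tips_total = tips, vessels_total = p$vessels_total,
    medium_mL_total = medium_mL, cost_per_sample = cost_ps)
}

#' Compare spread-plate and microplate consumables
#'
#' Pure arithmetic over two [protocol_spec()]s processing the same number of
#' samples: totals for tips, vessels and medium, per-sample cost, and the
#' spread/microplate ratio of each.
#'
#' @param spread,hts `protocol_spec` objects with equal `samples`.
#' @return A data frame with columns `quantity`, `spread`, `hts`, `ratio`.
#' @export
compare_protocols <- function(spread, hts) {
  stopifnot(inherits(spread, "protocol_spec"), inherits(hts, "protocol_spec"))
  if (spread$samples != hts$samples) {
    stop("both protocols must process the same number of samples",
         call. = FALSE)
  }
  a <- protocol_totals(spread)
  b <- protocol_totals(hts)
  data.frame(quantity = names(a), spread = unname(a), hts = unname(b),
             ratio = unname(ifelse(b > 0, a / b, NA_real_)),
             stringsAsFactors = FALSE)
}
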