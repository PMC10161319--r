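#' Unit-cost arithmetic
#'
#' Elementary operations of a bottom-up micro-costing exercise: pricing staff
#' time at an hourly rate, pricing counted consumables at a per-unit price,
#' amortising shared events (e.g. moving a mobile screening van) over the
#' screens they support, and moving prices between calendar years with a
#' health-service inflation index.
#'
#' All arithmetic is carried out in unrounded double precision; rounding to
#' 2 decimal places is a presentation concern and happens only in report
#' writers (see \code{\link{write_table3_report}}).
#'
#' @param minutes Task duration in minutes; must be non-negative.
#' @param hourly_rate Staff cost in GBP per hour; must be non-negative.
#' @return \code{time_cost}: cost in GBP, \code{minutes / 60 * hourly_rate}.
#' @examples
#' time_cost(21.25, 35)   # administrator data entry
#' time_cost(30, 123)     # consultant-led risk consultation
#' @export
time_cost <- function(minutes, hourly_rate) {
  check_nonnegative(minutes, "minutes")
  check_nonnegative(hourly_rate, "hourly_rate")
  minutes / 60 * hourly_rate
}

#' @rdname time_cost
#' @param quantity Count of units consumed (sheets, stamps, measurements);
#'   non-negative.
#' @param unit_price Price in GBP per unit; non-negative.
#' @return \code{quantity_cost}: cost in GBP, \code{quantity * unit_price}.
#' @export
quantity_cost <- function(quantity, unit_price) {
  check_nonnegative(quantity, "quantity")
  check_nonnegative(unit_price, "unit_price")
  quantity * unit_price
}

#' Per-screen share of a shared, repeated event
#'
#' Spreads the cost of an event that recurs at trust level (such as lowering
#' and re-raising the internet aerial each time a mobile screening van moves
#' site) over the individual screens performed. With \code{vans_per_trust}
#' vans each moving every \code{weeks_between_moves} weeks, a trust incurs
#' \code{vans_per_trust / weeks_between_moves} events per week, shared by
#' \code{screens_per_week} screens.
#'
#' @param event_cost Cost in GBP of one event (e.g. one van move).
#' @param vans_per_trust Number of vans operating per trust.
#' @param weeks_between_moves Average weeks between moves of one van; > 0.
#' @param screens_per_week Screens performed per week in the region; > 0.
#' @return Expected cost per screen in GBP.
#' @examples
#' amortized_event_cost(500, 2, 3, 580)  # ~0.57 per screen
#' @export
amortized_event_cost <- function(event_cost, vans_per_trust,
                                 weeks_between_moves, screens_per_week) {
  check_nonnegative(event_cost, "event_cost")
  check_nonnegative(vans_per_trust, "vans_per_trust")
  if (!is.numeric(weeks_between_moves) || weeks_between_moves <= 0)
    stop("weeks_between_moves must be > 0", call. = FALSE)
  if (!is.numeric(screens_per_week) || screens_per_week <= 0)
    stop("screens_per_week must be > 0", call. = FALSE)
  event_cost * (vans_per_trust / weeks_between_moves) / screens_per_week
}

#' Price-year inflation
#'
#' Re-expresses a cost observed in one price year in another, using a
#' health-service-specific index (e.g. the hospital and community services
#' inflation series). \code{series} is a named numeric vector mapping
#' calendar years to index values; the packaged fixture carries all unit
#' costs already at 2021 prices with an identity series, so inflation index
#' values are supplied via configuration and never embedded.
#'
#' @param value Cost in GBP at \code{from_year} prices.
#' @param from_year,to_year Calendar years; both must be present in
#'   \code{series}.
#' @param series Named numeric vector, year -> index value (all > 0).
#' @return \code{value * series[to_year] / series[from_year]}.
#' @examples
#' inflate(1, 2016, 2021, c("2016" = 100, "2021" = 110))
#' @export
inflate <- function(value, from_year, to_year, series) {
  series <- validate_inflation_series(series)
  yrs <- names(series)
  for (y in c(from_year, to_year)) {
    if (!as.character(y) %in% yrs)
      stop(sprintf("year %s not in inflation series (available: %s)",
                   y, paste(yrs, collapse = ", ")), call. = FALSE)
  }
  value * series[[as.character(to_year)]] / series[[as.character(from_year)]]
}

#' Read an inflation series from a JSON year-to-index map
#'
#' @param path Path to a JSON file of the form \code{{"2016": 100, ...}}.
#' @return Named numeric vector usable with \code{\link{inflate}}.
#' @export
read_inflation_series <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_inflation_series(unlist(x))
}

validate_inflation_series <- function(series) {
  if (is.null(names(series)) || any(!nzchar(names(series))))
    stop("inflation series must be a named year -> index map", call. = FALSE)
  series <- vapply(series, as.numeric, numeric(1))
  if (any(!is.finite(series)) || any(series <= 0))
    stop("inflation index values must all be positive", call. = FALSE)
  series
}

check_nonnegative <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("%s must be a non-negative number", field), call. = FALSE)
  invisible(x)
}

# Report-boundary rounding: money to 2 dp, probabilities to 4 dp.
round_money <- function(x) round(x, 2)
round_prob <- function(x) round(x, 4)

#' Enumerated unit kinds accepted in the unit-cost ledger
#' @export
UNIT_KINDS <- c("per_hour", "per_sheet", "per_stamp", "per_measurement",
                "per_move", "per_chip", "per_box", "per_item")
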