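#' National rollout cost and the value of implementation
#'
#' Scales a per-woman risk-stratification cost to an annual national
#' screening programme and quantifies what removing implementation barriers
#' is worth. The value of perfect implementation is the population-scaled
#' cost difference between the strategy as delivered with implementation
#' issues and as ideally delivered; the value of actual implementation
#' scales it by the fraction of barriers an initiative actually removes.
#'
#' @param n_women Women entering the programme per year (first screens).
#' @param uptake Proportion of invited women receiving the strategy, in
#'   [0,1].
#' @param per_woman_cost Per-woman strategy cost in GBP.
#' @return \code{annual_programme_cost}: annual cost in GBP,
#'   \code{n_women * uptake * per_woman_cost}.
#' @examples
#' annual_programme_cost(240000, 1, 6.64)   # ~1.6 million
#' @export
annual_programme_cost <- function(n_women, uptake, per_woman_cost) {
  check_nonnegative(n_women, "n_women")
  check_nonnegative(per_woman_cost, "per_woman_cost")
  if (uptake < 0 || uptake > 1)
    stop("uptake must be in [0,1]", call. = FALSE)
  n_women * uptake * per_woman_cost
}

#' @rdname annual_programme_cost
#' @param scenario Rollout scenario: list with \code{n_women_per_year},
#'   \code{uptake}, \code{per_woman_cost_perfect},
#'   \code{per_woman_cost_imperfect} and (for actual implementation)
#'   \code{barrier_removal_fraction}. See
#'   \code{\link{paper_rollout_scenario}}.
#' @return \code{value_of_perfect_implementation}: annual GBP value of
#'   removing all implementation barriers,
#'   \code{n * uptake * (imperfect - perfect)}.
#' @export
value_of_perfect_implementation <- function(scenario) {
  d <- scenario$per_woman_cost_imperfect - scenario$per_woman_cost_perfect
  if (d < 0)
    stop("imperfect per-woman cost below perfect: inputs inverted?",
         call. = FALSE)
  annual_programme_cost(scenario$n_women_per_year, scenario$uptake, d)
}

#' @rdname annual_programme_cost
#' @return \code{value_of_actual_implementation}:
#'   \code{barrier_removal_fraction} times the value of perfect
#'   implementation.
#' @export
value_of_actual_implementation <- function(scenario) {
  f <- scenario$barrier_removal_fraction
  if (f < 0 || f > 1)
    stop("barrier_removal_fraction must be in [0,1]", call. = FALSE)
  f * value_of_perfect_implementation(scenario)
}

#' Read a rollout scenario from JSON
#' @param path Path to a scenario JSON file.
#' @return Scenario list.
#' @export
read_rollout_scenario <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("n_women_per_year", "uptake", "per_woman_cost_perfect",
              "per_woman_cost_imperfect"))
    if (is.null(sc[[f]]))
      stop(sprintf("rollout scenario missing field %s", f), call. = FALSE)
  sc
}

# Presentation rounding used in rollout reporting: nearest 0.1 million GBP.
round_millions <- function(x) round(x / 1e6, 1)

#' Write a rollout report
#'
#' CSV with annual programme cost under perfect and imperfect
#' implementation and the values of perfect and actual implementation, both
#' exact (GBP) and rounded to 0.1 million GBP for presentation.
#'
#' @param scenario Rollout scenario list.
#' @param path Output CSV path.
#' @param provenance Named character vector of comment headers.
#' @return Invisibly, the path.
#' @export
write_rollout_report <- function(scenario, path, provenance = character(0)) {
  perfect <- annual_programme_cost(scenario$n_women_per_year,
                                   scenario$uptake,
                                   scenario$per_woman_cost_perfect)
  imperfect <- annual_programme_cost(scenario$n_women_per_year,
                                     scenario$uptake,
                                     scenario$per_woman_cost_imperfect)
  vopi <- value_of_perfect_implementation(scenario)
  voai <- value_of_actual_implementation(scenario)
  df <- data.frame(
    scenario = scenario$id,
    quantity = c("annual_cost_perfect", "annual_cost_imperfect",
                 "value_of_perfect_implementation",
                 "value_of_actual_implementation"),
    gbp = round_money(c(perfect, imperfect, vopi, voai)),
    gbp_millions = round_millions(c(perfect, imperfect, vopi, voai)))
  write_report_csv(df, path, provenance)
}
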