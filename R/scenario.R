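#' Market-share scenario sets
#'
#' Each scenario assumes that a fraction `market_share` of consumed products is
#' already low-sodium, so only the remaining `(1 - market_share)` of a
#' category's salt is available for umami substitution. The default set spans
#' shares of 0, 0.3, 0.6 and 0.9 (scenarios 1–4); the share is assumed uniform
#' across food categories.
#'
#' @param market_shares Numeric vector of market-share fractions, each in
#'   \[0, 1).
#' @return A tibble with columns `k` (1-based scenario index) and
#'   `market_share`.
#' @examples
#' default_scenarios()
#' @export
scenario_set <- function(market_shares) {
  if (!is.numeric(market_shares) || length(market_shares) == 0 ||
      any(market_shares < 0 | market_shares >= 1)) {
    abort_saltscen("market shares must be fractions in [0, 1)",
                   "saltscen_domain_error")
  }
  tibble::tibble(k = seq_along(market_shares), market_share = market_shares)
}

#' @rdname scenario_set
#' @export
default_scenarios <- function() {
  scenario_set(c(0, 0.3, 0.6, 0.9))
}

#' Lower/upper salt-reduction bounds for one category intake
#'
#' The achievable reduction in a category is the current category salt intake
#' scaled by the literature-derived reduction rate and by the fraction of
#' products not already low-sodium:
#' `reduction = S * rate * (1 - market_share)`,
#' evaluated at the category's lower and upper rates. The bounds are linear in
#' the intake and in `(1 - market_share)`, so a scenario with share `M`
#' yields exactly `(1 - M)` times the share-0 reduction.
#'
#' @param s_g_per_day Current category salt intake S (g/day), non-negative.
#' @param lower_rate,upper_rate Reduction-rate bounds (fractions,
#'   `lower_rate <= upper_rate`).
#' @param market_share Market share of low-sodium products (fraction in
#'   \[0, 1)). Arguments are recycled to a common length.
#' @return A tibble with columns `lower_g`, `upper_g` (g/day).
#' @examples
#' reduction_bounds(2.0, 0.17, 0.75, 0.3) # 0.238, 1.050
#' @export
reduction_bounds <- function(s_g_per_day, lower_rate, upper_rate, market_share) {
  if (any(s_g_per_day < 0, na.rm = TRUE)) {
    abort_saltscen("category intake must be non-negative", "saltscen_domain_error")
  }
  if (any(lower_rate > upper_rate)) {
    abort_saltscen("lower_rate must not exceed upper_rate", "saltscen_domain_error")
  }
  if (any(market_share < 0 | market_share >= 1)) {
    abort_saltscen("market_share must be in [0, 1)", "saltscen_domain_error")
  }
  avail <- 1 - market_share
  tibble::tibble(
    lower_g = s_g_per_day * lower_rate * avail,
    upper_g = s_g_per_day * upper_rate * avail
  )
}

#' Per-participant total reduction bounds under each scenario
#'
#' Joins category intakes with the registry rates, applies
#' [reduction_bounds()] per (participant, category, scenario), and sums over
#' categories. Unmatched ("none"-category) salt contributes nothing;
#' participants with no substitutable intake appear with zero bounds.
#'
#' @param category_intakes Output of [category_salt_intake()].
#' @param registry A validated registry tibble.
#' @param scenarios A scenario tibble, e.g. [default_scenarios()].
#' @return A tibble `participant_id`, `k`, `market_share`, `lower_g`,
#'   `upper_g`, one row per participant x scenario.
#' @export
individual_reduction <- function(category_intakes, registry,
                                 scenarios = default_scenarios()) {
  validate_registry(registry)
  matched <- category_intakes |>
    dplyr::filter(!is.na(.data$category_id)) |>
    dplyr::inner_join(
      dplyr::select(registry, "category_id", "lower_rate", "upper_rate"),
      by = "category_id"
    ) |>
    dplyr::cross_join(scenarios) |>
    dplyr::mutate(
      reduction_bounds(.data$salt_g_per_day, .data$lower_rate,
                       .data$upper_rate, .data$market_share)
    ) |>
    dplyr::summarise(
      lower_g = sum(.data$lower_g), upper_g = sum(.data$upper_g),
      .by = c("participant_id", "k", "market_share")
    )
  # participants whose diary has no substitutable foods still get (0, 0) rows
  everyone <- tidyr::crossing(
    participant_id = unique(category_intakes$participant_id), scenarios
  )
  everyone |>
    dplyr::left_join(matched, by = c("participant_id", "k", "market_share")) |>
    dplyr::mutate(
      lower_g = dplyr::coalesce(.data$lower_g, 0),
      upper_g = dplyr::coalesce(.data$upper_g, 0)
    ) |>
    dplyr::arrange(.data$participant_id, .data$k)
}
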