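#' Run the full salt-reduction scenario analysis
#'
#' End-to-end pipeline: filters the cohort to the analysis ages, computes each
#' individual's daily salt intake and its partition over the
#' umami-substitutable categories, applies the reduction-rate bounds under
#' each market-share scenario, and aggregates by gender and age band.
#'
#' @param participants A validated participants tibble (from
#'   [read_participants()] or [generate_cohort()]).
#' @param diary A validated diary tibble for those participants.
#' @param registry Category-rate registry; defaults to [default_registry()]
#'   (in which six categories are unmatchable until configured — see there).
#' @param scenarios Scenario tibble; defaults to [default_scenarios()].
#' @param min_age Minimum age of the analysis cohort (years).
#' @param rounded_rates Compute the percentage table from the
#'   printed-precision gram and intake tables (the published-table
#'   convention, default) or from unrounded summaries.
#' @return An object of class `salt_scenarios`: a list with the individual
#'   tables (`intake`, `category_intake`, `reduction`), the stratified
#'   summaries (`intake_summary`, `reduction_summary`, `rate_table`), and the
#'   inputs (`registry`, `scenarios`, `cohort`). Has [tidy()], [glance()],
#'   [ggplot2::autoplot()] and `print()` methods.
#' @examples
#' sim <- simulate_survey(seed = 42, cohort_cfg = cohort_config(
#'   n_per_stratum = tibble::tibble(
#'     gender = rep(c("female", "male"), each = 2),
#'     age_band = rep(c("20-29", "60-69"), 2), n = 40
#'   ), seed = 42
#' ))
#' fit <- run_salt_scenarios(sim$participants, sim$diary, sim$registry)
#' glance(fit)
#' @export
run_salt_scenarios <- function(participants, diary,
                               registry = default_registry(),
                               scenarios = default_scenarios(),
                               min_age = 20L,
                               rounded_rates = TRUE) {
  validate_registry(registry)
  cohort <- dplyr::filter(participants, .data$age >= min_age)
  if (nrow(cohort) == 0) {
    abort_saltscen("no participants at or above min_age", "saltscen_domain_error")
  }
  diary <- dplyr::semi_join(diary, cohort, by = "participant_id")

  intake <- daily_salt_intake(diary, cohort) |>
    dplyr::left_join(dplyr::select(cohort, "participant_id", "gender", "age"),
                     by = "participant_id")
  cat_intake <- category_salt_intake(diary, cohort, registry)
  reduction <- individual_reduction(cat_intake, registry, scenarios) |>
    dplyr::left_join(dplyr::select(cohort, "participant_id", "gender", "age"),
                     by = "participant_id")

  intake_summary <- summarize_intake(intake)
  reduction_summary <- summarize_reduction(reduction)
  rate_table <- reduction_rate_table(reduction_summary, intake_summary,
                                     rounded = rounded_rates)

  structure(
    list(
      cohort = cohort,
      intake = intake,
      category_intake = cat_intake,
      reduction = reduction,
      intake_summary = intake_summary,
      reduction_summary = reduction_summary,
      rate_table = rate_table,
      registry = registry,
      scenarios = scenarios,
      rounded_rates = rounded_rates
    ),
    class = "salt_scenarios"
  )
}

#' @export
print.salt_scenarios <- function(x, ...) {
  all_rows <- dplyr::filter(x$rate_table, .data$stratum == "total",
                            .data$age_band == "All")
  cat(sprintf(
    "<salt_scenarios> %d participants, %d scenarios, %d categories\n",
    nrow(x$cohort), nrow(x$scenarios), nrow(x$registry)
  ))
  intake_all <- dplyr::filter(x$intake_summary, .data$stratum == "total",
                              .data$age_band == "All")
  cat(sprintf("mean intake (all adults): %.2f g/day (SD %.2f)\n",
              intake_all$mean_intake, intake_all$sd_intake))
  for (i in seq_len(nrow(all_rows))) {
    cat(sprintf(
      "scenario %d (share %d%%): reduction %.2f-%.2f g/day (%.2f-%.2f%%)\n",
      all_rows$k[i], round(all_rows$market_share[i] * 100),
      all_rows$mean_lower_g[i], all_rows$mean_upper_g[i],
      all_rows$rate_lower_pct[i], all_rows$rate_upper_pct[i]
    ))
  }
  invisible(x)
}

#' Tidy a salt-scenario analysis
#'
#' @param x A `salt_scenarios` object.
#' @param table Which summary to return: `"rates"` (reduction rates in %,
#'   default), `"reduction"` (g/day) or `"intake"`.
#' @param ... Unused.
#' @return A tibble, one row per stratum x age band (x scenario).
#' @export
tidy.salt_scenarios <- function(x, table = c("rates", "reduction", "intake"),
                                ...) {
  table <- match.arg(table)
  switch(table,
    rates = x$rate_table,
    reduction = x$reduction_summary,
    intake = x$intake_summary
  )
}

#' One-row overview of a salt-scenario analysis
#'
#' @param x A `salt_scenarios` object.
#' @param ... Unused.
#' @return A one-row tibble: cohort size, all-adult mean intake, and the
#'   share-0 scenario's reduction bounds in g/day and percent.
#' @export
glance.salt_scenarios <- function(x, ...) {
  intake_all <- dplyr::filter(x$intake_summary, .data$stratum == "total",
                              .data$age_band == "All")
  s1 <- dplyr::filter(x$rate_table, .data$stratum == "total",
                      .data$age_band == "All",
                      .data$market_share == min(.data$market_share))
  tibble::tibble(
    n = intake_all$n,
    mean_intake = intake_all$mean_intake,
    sd_intake = intake_all$sd_intake,
    reduction_lower_g = s1$mean_lower_g,
    reduction_upper_g = s1$mean_upper_g,
    rate_lower_pct = s1$rate_lower_pct,
    rate_upper_pct = s1$rate_upper_pct
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
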