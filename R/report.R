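#' Decade age bands for adult reporting
#'
#' Reporting strata use decade bands with an inclusive lower edge, 20-29
#' through 70-79, and an open top band 80+. The cohort must already be
#' restricted to ages 20 and over.
#'
#' @param age Integer vector of ages in years, all `>= 20`.
#' @return A factor with levels `r paste(c("20-29", "...", "80+"), collapse = ", ")`.
#' @examples
#' assign_age_band(c(20, 79, 80))
#' @export
assign_age_band <- function(age) {
  if (any(age < 20, na.rm = TRUE)) {
    abort_saltscen("age bands are defined for ages >= 20; filter the cohort first",
                   "saltscen_domain_error")
  }
  cut(
    age,
    breaks = c(seq(20, 80, by = 10), Inf),
    labels = age_band_levels(),
    right = FALSE, include.lowest = TRUE
  )
}

#' @rdname assign_age_band
#' @export
age_band_levels <- function() {
  c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")
}

# internal: iterate a per-individual table over the three gender strata
# (total = everyone, women, men), summarising by age band plus an "All" row.
# Empty bands within a stratum are omitted with a warning, never zero-filled.
stratified_summary <- function(df, summarise_fn, extra_by = character()) {
  strata <- list(
    total = df,
    women = dplyr::filter(df, .data$gender == "female"),
    men   = dplyr::filter(df, .data$gender == "male")
  )
  out <- purrr::imap(strata, function(d, label) {
    if (nrow(d) == 0) {
      warning(sprintf("stratum '%s' is empty; omitted", label), call. = FALSE)
      return(NULL)
    }
    d <- dplyr::mutate(d, age_band = as.character(assign_age_band(.data$age)))
    missing_bands <- setdiff(age_band_levels(), unique(d$age_band))
    if (length(missing_bands) > 0) {
      warning(
        sprintf("stratum '%s': no individuals in band(s) %s; omitted",
                label, paste(missing_bands, collapse = ", ")),
        call. = FALSE
      )
    }
    bands <- summarise_fn(d, c("age_band", extra_by))
    all_row <- summarise_fn(dplyr::mutate(d, age_band = "All"),
                            c("age_band", extra_by))
    dplyr::mutate(dplyr::bind_rows(bands, all_row), stratum = label)
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(
      stratum = factor(.data$stratum, levels = c("total", "women", "men")),
      age_band = factor(.data$age_band, levels = c(age_band_levels(), "All"))
    ) |>
    dplyr::relocate("stratum", "age_band") |>
    dplyr::arrange(.data$stratum, .data$age_band)
}

#' Gender- and age-stratified current salt intake
#'
#' Unweighted arithmetic mean and sample standard deviation (n - 1 denominator)
#' of individual daily salt intake, for strata total/women/men crossed with
#' the decade age bands of [assign_age_band()] plus an "All" row per stratum.
#' The SD is `NA` for single-member strata.
#'
#' @param intakes A tibble of individuals with columns `participant_id`,
#'   `gender` (female/male), `age`, `salt_g_per_day` — e.g.
#'   [daily_salt_intake()] joined with the participants table.
#' @return A tibble `stratum`, `age_band`, `n`, `mean_intake`, `sd_intake`.
#' @export
summarize_intake <- function(intakes) {
  check_columns(intakes, c("gender", "age", "salt_g_per_day"), "intake table")
  stratified_summary(intakes, function(d, by) {
    dplyr::summarise(
      d,
      n = dplyr::n(),
      mean_intake = mean(.data$salt_g_per_day),
      sd_intake = if (dplyr::n() >= 2) stats::sd(.data$salt_g_per_day) else NA_real_,
      .by = dplyr::all_of(by)
    )
  })
}

#' Gender- and age-stratified mean reduction bounds
#'
#' Unweighted stratum means of the per-participant lower and upper reduction
#' totals from [individual_reduction()], for each scenario.
#'
#' @param reductions A tibble with columns `participant_id`, `gender`, `age`,
#'   `k`, `market_share`, `lower_g`, `upper_g` — e.g. [individual_reduction()]
#'   joined with the participants table.
#' @return A tibble `stratum`, `age_band`, `k`, `market_share`, `n`,
#'   `mean_lower_g`, `mean_upper_g`.
#' @export
summarize_reduction <- function(reductions) {
  check_columns(reductions,
                c("gender", "age", "k", "market_share", "lower_g", "upper_g"),
                "reduction table")
  stratified_summary(reductions, function(d, by) {
    dplyr::summarise(
      d,
      n = dplyr::n(),
      mean_lower_g = mean(.data$lower_g),
      mean_upper_g = mean(.data$upper_g),
      .by = dplyr::all_of(by)
    )
  }, extra_by = c("k", "market_share")) |>
    dplyr::arrange(.data$stratum, .data$k, .data$age_band)
}

# internal: printed precision of the gram table — 2 decimals, except 3 for
# high-share scenarios whose values would otherwise lose a significant digit
reduction_digits <- function(market_share) {
  ifelse(market_share > 0.6, 3L, 2L)
}

#' Round summary tables at their printed precision
#'
#' Applies half-up rounding at the reporting precision: intake means/SDs at 2
#' decimals; reduction grams at 2 decimals for scenarios with market share
#' <= 0.6 and 3 decimals above (where values shrink by an order of magnitude).
#'
#' @param reduction_summary Output of [summarize_reduction()].
#' @param intake_summary Output of [summarize_intake()].
#' @return The input tibble with its value columns rounded.
#' @export
round_reduction_table <- function(reduction_summary) {
  d <- reduction_digits(reduction_summary$market_share)
  rhu_at <- function(x) {
    ifelse(d == 3L, round_half_up(x, 3), round_half_up(x, 2))
  }
  dplyr::mutate(
    reduction_summary,
    mean_lower_g = rhu_at(.data$mean_lower_g),
    mean_upper_g = rhu_at(.data$mean_upper_g)
  )
}

#' @rdname round_reduction_table
#' @export
round_intake_table <- function(intake_summary) {
  dplyr::mutate(
    intake_summary,
    mean_intake = round_half_up(.data$mean_intake, 2),
    sd_intake = round_half_up(.data$sd_intake, 2)
  )
}

#' Reduction rates as a percentage of current intake
#'
#' Expresses the stratum mean reductions as a percentage of the stratum's
#' current mean intake: `rate = 100 * mean reduction / mean intake` (a ratio
#' of stratum means, not a mean of individual ratios), rounded half-up to 2
#' decimals. By default both inputs are first rounded at their printed
#' precision ([round_reduction_table()], [round_intake_table()]): this
#' table-arithmetic convention is what published survey tables are built
#' from, and is reproducible by a reader from the printed tables alone.
#' `rounded = FALSE` computes the rates from the unrounded summaries instead.
#'
#' @param reduction_summary Output of [summarize_reduction()] (or a comparable
#'   table of printed values).
#' @param intake_summary Output of [summarize_intake()] (or printed values).
#' @param rounded Round both inputs at printed precision first (default TRUE).
#' @return `reduction_summary` with columns `rate_lower_pct`,
#'   `rate_upper_pct` added.
#' @export
reduction_rate_table <- function(reduction_summary, intake_summary,
                                 rounded = TRUE) {
  need <- dplyr::distinct(reduction_summary, .data$stratum, .data$age_band)
  have <- dplyr::distinct(intake_summary, .data$stratum, .data$age_band)
  gap <- dplyr::anti_join(need, have, by = c("stratum", "age_band"))
  if (nrow(gap) > 0) {
    abort_saltscen(
      sprintf("intake table lacks stratum/band: %s",
              paste(gap$stratum, gap$age_band, sep = "/", collapse = ", ")),
      "saltscen_validation_error"
    )
  }
  if (rounded) {
    reduction_summary <- round_reduction_table(reduction_summary)
    intake_summary <- round_intake_table(intake_summary)
  }
  reduction_summary |>
    dplyr::left_join(
      dplyr::select(intake_summary, "stratum", "age_band", "mean_intake"),
      by = c("stratum", "age_band")
    ) |>
    dplyr::mutate(
      rate_lower_pct = round_half_up(100 * .data$mean_lower_g / .data$mean_intake, 2),
      rate_upper_pct = round_half_up(100 * .data$mean_upper_g / .data$mean_intake, 2)
    )
}

#' Write the three report tables to delimited text files
#'
#' Emits the survey-style tables: current intake by stratum
#' (`table2_intake.tsv`), mean reduction bounds in g/day by scenario
#' (`table3_reduction_g.tsv`), reduction rates in percent
#' (`table4_reduction_pct.tsv`), and a machine-readable long-format file with
#' the unrounded values (`reduction_long.csv`). Bounds are printed as
#' "lower-upper" at the printed precision (see [round_reduction_table()]).
#'
#' @param intake_summary Output of [summarize_intake()].
#' @param reduction_summary Output of [summarize_reduction()].
#' @param rate_table Output of [reduction_rate_table()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the files written.
#' @export
format_tables <- function(intake_summary, reduction_summary, rate_table, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  # inputs are pre-rounded half-up at `digits`; this only formats
  fmt <- function(x, digits) {
    ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
  }

  t2 <- round_intake_table(intake_summary) |>
    dplyr::transmute(
      stratum = .data$stratum, age_band = .data$age_band, n = .data$n,
      mean_salt_g_day = fmt(.data$mean_intake, 2),
      sd_salt_g_day = fmt(.data$sd_intake, 2)
    )

  grams <- round_reduction_table(reduction_summary) |>
    dplyr::mutate(
      digits = reduction_digits(.data$market_share),
      cell = paste0(fmt(.data$mean_lower_g, .data$digits), "-",
                    fmt(.data$mean_upper_g, .data$digits)),
      scenario = paste0("scenario_", .data$k, "_share_",
                        as.character(.data$market_share))
    )
  t3 <- tidyr::pivot_wider(
    dplyr::select(grams, "stratum", "age_band", "scenario", "cell"),
    names_from = "scenario", values_from = "cell"
  )

  rates <- rate_table |>
    dplyr::mutate(
      cell = paste0(fmt(.data$rate_lower_pct, 2), "-", fmt(.data$rate_upper_pct, 2)),
      scenario = paste0("scenario_", .data$k, "_share_",
                        as.character(.data$market_share))
    )
  t4 <- tidyr::pivot_wider(
    dplyr::select(rates, "stratum", "age_band", "scenario", "cell"),
    names_from = "scenario", values_from = "cell"
  )

  long <- dplyr::left_join(
    reduction_summary,
    dplyr::select(intake_summary, "stratum", "age_band",
                  "mean_intake", "sd_intake"),
    by = c("stratum", "age_band")
  )

  paths <- c(
    table2 = file.path(dir, "table2_intake.tsv"),
    table3 = file.path(dir, "table3_reduction_g.tsv"),
    table4 = file.path(dir, "table4_reduction_pct.tsv"),
    long = file.path(dir, "reduction_long.csv")
  )
  tryCatch({
    readr::write_tsv(t2, paths[["table2"]])
    readr::write_tsv(t3, paths[["table3"]])
    readr::write_tsv(t4, paths[["table4"]])
    readr::write_csv(long, paths[["long"]])
  }, error = function(e) {
    abort_saltscen(
      sprintf("failed writing report tables under '%s': %s", dir,
              conditionMessage(e)),
      "saltscen_io_error"
    )
  })
  invisible(paths)
}
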