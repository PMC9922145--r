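# mg sodium -> g sodium chloride equivalent
SALT_PER_MG_SODIUM <- 2.54 / 1000

#' Convert sodium mass to salt equivalent
#'
#' Salt equivalent (g) is defined as sodium (mg) x 2.54/1000, the molar-mass
#' ratio of sodium chloride to sodium combined with the mg-to-g unit change.
#'
#' @param sodium_mg Numeric vector of sodium masses in milligrams; must be
#'   non-negative.
#' @return Salt-equivalent masses in grams.
#' @examples
#' salt_equivalent(1000) # 2.54
#' @export
salt_equivalent <- function(sodium_mg) {
  if (!is.numeric(sodium_mg)) {
    abort_saltscen("sodium_mg must be numeric", "saltscen_domain_error")
  }
  if (any(sodium_mg < 0, na.rm = TRUE)) {
    abort_saltscen("sodium_mg must be non-negative", "saltscen_domain_error")
  }
  sodium_mg * SALT_PER_MG_SODIUM
}

#' Read and validate a participants table
#'
#' Expects a delimited text file (comma or tab, autodetected from the header
#' line unless `delim` is given) with columns `participant_id`, `gender`
#' (`female`/`male`), `age` (integer years) and `n_diary_days` (3 or 4).
#'
#' @param path Path to the participants file.
#' @param delim Field delimiter; `NULL` to autodetect `,` vs tab.
#' @return A validated tibble with one row per participant.
#' @seealso [read_diary()], [validate_participants()]
#' @export
read_participants <- function(path, delim = NULL) {
  df <- read_delimited(path, delim)
  validate_participants(df)
}

#' Validate an in-memory participants table
#'
#' Applied by [read_participants()] and reusable on programmatically built
#' cohorts (e.g. from [generate_cohort()]). Rejects missing columns, duplicate
#' ids, unparseable gender or age, negative ages, and diary lengths other than
#' 3 or 4 days; row-level problems are reported with their (1-based, header
#' excluded) row numbers.
#'
#' @param df A data frame with columns `participant_id`, `gender`, `age`,
#'   `n_diary_days`.
#' @return A tibble with typed columns (`gender` as factor female/male).
#' @export
validate_participants <- function(df) {
  check_columns(df, c("participant_id", "gender", "age", "n_diary_days"),
                "participants table")
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) {
    return(dplyr::mutate(
      df,
      participant_id = as.character(.data$participant_id),
      gender = factor(character(), levels = c("female", "male")),
      age = integer(), n_diary_days = integer()
    ))
  }
  dup <- unique(df$participant_id[duplicated(df$participant_id)])
  if (length(dup) > 0) {
    abort_saltscen(
      sprintf("duplicate participant_id: %s", paste(dup, collapse = ", ")),
      "saltscen_validation_error"
    )
  }
  gender <- tolower(trimws(as.character(df$gender)))
  bad <- which(!gender %in% c("female", "male"))
  if (length(bad) > 0) {
    abort_saltscen(
      sprintf("unparseable gender at row(s) %s (need female/male)",
              paste(utils::head(bad, 5), collapse = ", ")),
      "saltscen_validation_error"
    )
  }
  age <- suppressWarnings(as.numeric(df$age))
  bad <- which(is.na(age) | age < 0 | age != floor(age))
  if (length(bad) > 0) {
    abort_saltscen(
      sprintf("unparseable or negative age at row(s) %s",
              paste(utils::head(bad, 5), collapse = ", ")),
      "saltscen_validation_error"
    )
  }
  days <- suppressWarnings(as.integer(df$n_diary_days))
  bad <- which(is.na(days) | !days %in% c(3L, 4L))
  if (length(bad) > 0) {
    abort_saltscen(
      sprintf("n_diary_days must be 3 or 4; offending row(s): %s",
              paste(utils::head(bad, 5), collapse = ", ")),
      "saltscen_validation_error"
    )
  }
  tibble::tibble(
    participant_id = as.character(df$participant_id),
    gender = factor(gender, levels = c("female", "male")),
    age = as.integer(age),
    n_diary_days = days
  )
}

#' Read and validate a food-diary table
#'
#' Expects a delimited text file with columns `participant_id`, `day`,
#' `food_code`, `main_group_code`, `amount_g`, `sodium_mg_per_100g` and
#' optionally `sodium_mg_total` (per-record total sodium; takes precedence
#' over density x amount where present, since survey extracts ship either
#' form).
#'
#' @param path Path to the diary file.
#' @param participants A validated participants tibble; every diary record
#'   must reference one of its ids and a day within that participant's
#'   recorded diary length.
#' @param delim Field delimiter; `NULL` to autodetect.
#' @return A validated diary tibble.
#' @export
read_diary <- function(path, participants, delim = NULL) {
  df <- read_delimited(path, delim)
  validate_diary(df, participants)
}

#' Validate an in-memory food-diary table
#'
#' @inheritParams read_diary
#' @param df A data frame with the diary columns (see [read_diary()]).
#' @return A typed diary tibble.
#' @export
validate_diary <- function(df, participants) {
  check_columns(
    df,
    c("participant_id", "day", "food_code", "main_group_code",
      "amount_g", "sodium_mg_per_100g"),
    "diary table"
  )
  df <- tibble::as_tibble(df)
  df$participant_id <- as.character(df$participant_id)
  if (nrow(df) == 0) {
    return(df)
  }
  orphan <- setdiff(unique(df$participant_id), participants$participant_id)
  if (length(orphan) > 0) {
    abort_saltscen(
      sprintf("diary references unknown participant(s): %s",
              paste(orphan, collapse = ", ")),
      "saltscen_validation_error"
    )
  }
  day <- suppressWarnings(as.integer(df$day))
  limit <- participants$n_diary_days[
    match(df$participant_id, participants$participant_id)
  ]
  bad <- which(is.na(day) | day < 1L | day > limit)
  if (length(bad) > 0) {
    abort_saltscen(
      sprintf("diary day out of 1..n_diary_days range at row(s): %s",
              paste(utils::head(bad, 5), collapse = ", ")),
      "saltscen_validation_error"
    )
  }
  amount <- suppressWarnings(as.numeric(df$amount_g))
  dens <- suppressWarnings(as.numeric(df$sodium_mg_per_100g))
  bad <- which(is.na(amount) | amount < 0 | is.na(dens) | dens < 0)
  if (length(bad) > 0) {
    abort_saltscen(
      sprintf("negative or unparseable amount_g/sodium_mg_per_100g at row(s): %s",
              paste(utils::head(bad, 5), collapse = ", ")),
      "saltscen_validation_error"
    )
  }
  out <- df
  out$day <- day
  out$food_code <- as.character(out$food_code)
  out$main_group_code <- as.integer(out$main_group_code)
  out$amount_g <- amount
  out$sodium_mg_per_100g <- dens
  if ("sodium_mg_total" %in% names(out)) {
    tot <- suppressWarnings(as.numeric(out$sodium_mg_total))
    if (any(!is.na(tot) & tot < 0)) {
      abort_saltscen("negative sodium_mg_total", "saltscen_validation_error")
    }
    out$sodium_mg_total <- tot
  }
  out
}

# internal: per-record sodium in mg; an explicit total overrides density x amount
record_sodium_mg <- function(diary) {
  base <- diary$amount_g * diary$sodium_mg_per_100g / 100
  if ("sodium_mg_total" %in% names(diary)) {
    dplyr::coalesce(diary$sodium_mg_total, base)
  } else {
    base
  }
}

#' Mean daily salt intake per participant
#'
#' Sums each participant's sodium over all diary records, converts to salt
#' equivalent, and divides by that participant's own recorded diary length
#' (3 or 4 days) — not a fixed 4 — so short diaries are not deflated.
#' Sampling weights are deliberately not supported: the pipeline describes the
#' unweighted individual-level intake distribution.
#'
#' @param diary A validated diary tibble.
#' @param participants A validated participants tibble; every participant must
#'   have at least one diary record (a silent zero would hide linkage bugs).
#' @return A tibble `participant_id`, `salt_g_per_day`, one row per
#'   participant in `participants`.
#' @examples
#' p <- validate_participants(data.frame(
#'   participant_id = "P1", gender = "female", age = 34, n_diary_days = 4
#' ))
#' d <- validate_diary(data.frame(
#'   participant_id = "P1", day = 1, food_code = "14R", main_group_code = 14,
#'   amount_g = 100, sodium_mg_per_100g = 1000
#' ), p)
#' daily_salt_intake(d, p) # 2.54 / 4 = 0.635 g/day
#' @export
daily_salt_intake <- function(diary, participants) {
  missing <- setdiff(participants$participant_id, diary$participant_id)
  if (length(missing) > 0) {
    abort_saltscen(
      sprintf("no diary data for participant(s): %s",
              paste(utils::head(missing, 10), collapse = ", ")),
      "saltscen_no_diary_error"
    )
  }
  diary |>
    dplyr::mutate(sodium_mg = record_sodium_mg(diary)) |>
    dplyr::summarise(sodium_mg = sum(.data$sodium_mg), .by = "participant_id") |>
    dplyr::left_join(
      dplyr::select(participants, "participant_id", "n_diary_days"),
      by = "participant_id"
    ) |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      salt_g_per_day = salt_equivalent(.data$sodium_mg) / .data$n_diary_days
    )
}

#' Partition daily salt intake across substitutable categories
#'
#' Resolves each diary record to at most one registry category via
#' [match_category()] and aggregates salt intake per participant and category,
#' using the same per-person day divisor as [daily_salt_intake()]. Salt from
#' unmatched records is reported under `category_id = NA` (the "none"
#' category), which is emitted for every participant so the rows always
#' partition the participant's total intake exactly.
#'
#' @inheritParams daily_salt_intake
#' @param registry A validated registry tibble.
#' @return A tibble `participant_id`, `category_id` (`NA` = not
#'   umami-substitutable), `salt_g_per_day`.
#' @export
category_salt_intake <- function(diary, participants, registry) {
  totals <- daily_salt_intake(diary, participants)
  per_cat <- diary |>
    dplyr::mutate(
      sodium_mg = record_sodium_mg(diary),
      category_id = match_category(.data$food_code, .data$main_group_code, registry)
    ) |>
    dplyr::filter(!is.na(.data$category_id)) |>
    dplyr::summarise(
      sodium_mg = sum(.data$sodium_mg),
      .by = c("participant_id", "category_id")
    ) |>
    dplyr::left_join(
      dplyr::select(participants, "participant_id", "n_diary_days"),
      by = "participant_id"
    ) |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      category_id = .data$category_id,
      salt_g_per_day = salt_equivalent(.data$sodium_mg) / .data$n_diary_days
    )
  none <- totals |>
    dplyr::left_join(
      dplyr::summarise(per_cat, matched = sum(.data$salt_g_per_day),
                       .by = "participant_id"),
      by = "participant_id"
    ) |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      category_id = NA_integer_,
      salt_g_per_day = .data$salt_g_per_day - dplyr::coalesce(.data$matched, 0)
    )
  dplyr::bind_rows(per_cat, none) |>
    dplyr::arrange(.data$participant_id, .data$category_id)
}

# internal: read a comma- or tab-delimited text file with a header row
read_delimited <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort_saltscen(sprintf("file not found: %s", path), "saltscen_io_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
}
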