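test_that("sodium-to-salt conversion follows the 2.54/1000 definition", {
  expect_equal(salt_equivalent(1000), 2.54)
  expect_equal(salt_equivalent(0), 0)
  expect_equal(salt_equivalent(2000), 5.08)
  expect_equal(salt_equivalent(c(500, 1500)), c(1.27, 3.81))
  expect_error(salt_equivalent(-1), class = "saltscen_domain_error")
})

test_that("participants reader parses rows and rejects malformed tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,gender,age,n_diary_days", "P1,female,34,4"), path)
  p <- read_participants(path)
  expect_equal(nrow(p), 1L)
  expect_equal(p$participant_id, "P1")
  expect_equal(as.character(p$gender), "female")
  expect_equal(p$age, 34L)
  expect_equal(p$n_diary_days, 4L)

  writeLines("participant_id,gender,age,n_diary_days", path)
  expect_equal(nrow(read_participants(path)), 0L)

  writeLines(c("participant_id,gender,age", "P1,female,34"), path)
  expect_error(read_participants(path), "n_diary_days",
               class = "saltscen_schema_error")

  writeLines(c("participant_id,gender,age,n_diary_days",
               "P1,female,34,4", "P1,male,40,4"), path)
  expect_error(read_participants(path), "duplicate",
               class = "saltscen_validation_error")

  writeLines(c("participant_id,gender,age,n_diary_days",
               "P1,female,34,4", "P2,unknown,40,4"), path)
  expect_error(read_participants(path), "row\\(s\\) 2",
               class = "saltscen_validation_error")

  writeLines(c("participant_id,gender,age,n_diary_days", "P1,female,-3,4"),
             path)
  expect_error(read_participants(path), "age",
               class = "saltscen_validation_error")
})

test_that("diary reader enforces referential integrity and ranges", {
  p <- make_participants("P1")
  ok <- validate_diary(make_record("P1"), p)
  expect_equal(nrow(ok), 1L)
  expect_equal(ok$food_code, "14R")

  expect_error(validate_diary(make_record("P9"), p), "P9",
               class = "saltscen_validation_error")
  expect_error(validate_diary(make_record("P1", day = 5L), p),
               class = "saltscen_validation_error")
  expect_error(validate_diary(make_record("P1", amount_g = -2), p),
               class = "saltscen_validation_error")
  # day 4 invalid for a 3-day diary
  p3 <- make_participants("Q1", n_diary_days = 3L)
  expect_error(
    validate_diary(make_record("Q1", day = 4L), p3),
    class = "saltscen_validation_error"
  )
})

test_that("daily intake divides by the participant's own diary length", {
  p <- make_participants("P1")
  d <- make_record("P1", amount_g = 100, sodium_mg_per_100g = 1000)
  expect_equal(daily_salt_intake(d, p)$salt_g_per_day, 2.54 / 4)

  # 1500 + 2500 mg over a 2-day recording window is averaged over the
  # recorded days, never a constant 4
  p2 <- validate_participants(tibble::tibble(
    participant_id = "P2", gender = "male", age = 50, n_diary_days = 3
  ))
  d2 <- dplyr::bind_rows(
    make_record("P2", day = 1L, amount_g = 150, sodium_mg_per_100g = 1000),
    make_record("P2", day = 2L, amount_g = 250, sodium_mg_per_100g = 1000)
  )
  # treat as if the recorded day count were 2 by constructing such a cohort:
  # diary length must itself be 3 or 4, so check via the 3- vs 4-day ratio
  expect_equal(daily_salt_intake(d2, p2)$salt_g_per_day, 4000 * 2.54 / 1000 / 3)

  p4 <- make_participants("P2", gender = "male", age = 50, n_diary_days = 4L)
  expect_equal(
    daily_salt_intake(d2, p2)$salt_g_per_day,
    daily_salt_intake(d2, p4)$salt_g_per_day * 4 / 3
  )

  expect_error(
    daily_salt_intake(d2, make_participants(c("P2", "P3"), age = 50)),
    "no diary data",
    class = "saltscen_no_diary_error"
  )
})

test_that("explicit per-record sodium totals take precedence over density", {
  p <- make_participants("P1")
  d <- make_record("P1", amount_g = 100, sodium_mg_per_100g = 1000)
  d$sodium_mg_total <- 500 # contradicts density x amount on purpose
  expect_equal(daily_salt_intake(d, p)$salt_g_per_day, 500 * 2.54 / 1000 / 4)
  d$sodium_mg_total <- NA_real_ # falls back per record
  expect_equal(daily_salt_intake(d, p)$salt_g_per_day, 2.54 / 4)
})

test_that("category partition matches hand arithmetic and conserves totals", {
  reg <- default_registry()
  p <- make_participants("P1")
  d <- make_record("P1", amount_g = 100, sodium_mg_per_100g = 700)
  ci <- category_salt_intake(d, p, reg)
  cheese <- ci$salt_g_per_day[!is.na(ci$category_id) & ci$category_id == 1]
  none <- ci$salt_g_per_day[is.na(ci$category_id)]
  expect_equal(cheese, 100 * 700 / 100 * 2.54 / 1000 / 4) # 0.4445
  expect_equal(none, 0)

  # all-unmatched diary: a single none-category row carrying the total
  d99 <- make_record("P1", food_code = "99A", main_group_code = 99L)
  ci99 <- category_salt_intake(d99, p, reg)
  expect_equal(nrow(ci99), 1L)
  expect_true(is.na(ci99$category_id))
  expect_equal(ci99$salt_g_per_day, daily_salt_intake(d99, p)$salt_g_per_day)
})

test_that("category intakes partition the total and scale linearly", {
  fx <- random_fixture(n_people = 25, seed = 202)
  reg <- synthetic_prefix_overlay()
  ci <- category_salt_intake(fx$diary, fx$participants, reg)
  totals <- daily_salt_intake(fx$diary, fx$participants)
  sums <- dplyr::summarise(ci, s = sum(salt_g_per_day), .by = participant_id)
  joined <- dplyr::left_join(totals, sums, by = "participant_id")
  expect_equal(joined$s, joined$salt_g_per_day, tolerance = 1e-12)

  doubled <- dplyr::mutate(fx$diary, amount_g = amount_g * 2)
  ci2 <- category_salt_intake(doubled, fx$participants, reg) |>
    dplyr::arrange(participant_id, category_id)
  ci1 <- dplyr::arrange(ci, participant_id, category_id)
  expect_equal(ci2$salt_g_per_day, 2 * ci1$salt_g_per_day)
})

test_that("write -> read round trip is lossless", {
  fx <- random_fixture(n_people = 10, seed = 303)
  pfile <- withr::local_tempfile(fileext = ".csv")
  dfile <- withr::local_tempfile(fileext = ".tsv")
  readr::write_csv(fx$participants, pfile)
  readr::write_tsv(fx$diary, dfile)
  p2 <- read_participants(pfile)
  d2 <- read_diary(dfile, p2)
  expect_equal(as.data.frame(p2), as.data.frame(fx$participants))
  expect_equal(as.data.frame(d2), as.data.frame(fx$diary))
})
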