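test_that("age bands are decades with an inclusive lower edge and 80+ top", {
  expect_equal(as.character(assign_age_band(c(20, 29, 30, 79, 80, 95))),
               c("20-29", "20-29", "30-39", "70-79", "80+", "80+"))
  expect_error(assign_age_band(19), class = "saltscen_domain_error")
})

test_that("intake summaries use unweighted means and n-1 standard deviations", {
  people <- tibble::tibble(
    participant_id = c("A", "B", "C", "D"),
    gender = factor(c("female", "female", "female", "male"),
                    levels = c("female", "male")),
    age = c(25L, 25L, 27L, 41L),
    salt_g_per_day = c(4, 5, 6, 5)
  )
  s <- suppressWarnings(summarize_intake(people))
  w2029 <- dplyr::filter(s, stratum == "women", age_band == "20-29")
  expect_equal(w2029$n, 3L)
  expect_equal(w2029$mean_intake, 5)
  expect_equal(w2029$sd_intake, 1) # sd of {4,5,6} with n-1 denominator

  # degenerate stratum: mean defined, sd reported as missing
  m4049 <- dplyr::filter(s, stratum == "men", age_band == "40-49")
  expect_equal(m4049$mean_intake, 5)
  expect_true(is.na(m4049$sd_intake))

  # empty bands are omitted with a warning, not zero-filled
  warns <- testthat::capture_warnings(summarize_intake(people))
  expect_true(any(grepl("omitted", warns)))
  expect_false("30-39" %in% as.character(s$age_band[s$stratum == "women"]))

  # the All row is the plain mean over stratum members and recombines the
  # size-weighted band rows
  all_total <- dplyr::filter(s, stratum == "total", age_band == "All")
  expect_equal(all_total$mean_intake, mean(people$salt_g_per_day))
  bands <- dplyr::filter(s, stratum == "total", age_band != "All")
  expect_equal(sum(bands$n * bands$mean_intake) / sum(bands$n),
               all_total$mean_intake)
  # women and men recombine to the total row
  womenmen <- dplyr::filter(s, stratum != "total", age_band == "All")
  expect_equal(sum(womenmen$n * womenmen$mean_intake) / sum(womenmen$n),
               all_total$mean_intake)
})

test_that("reduction summaries average individual bounds by stratum", {
  one <- tibble::tibble(
    participant_id = "A",
    gender = factor("female", levels = c("female", "male")),
    age = 25L, k = 1L, market_share = 0, lower_g = 0.4, upper_g = 0.9
  )
  s1 <- suppressWarnings(summarize_reduction(one))
  row <- dplyr::filter(s1, stratum == "total", age_band == "All")
  expect_equal(c(row$mean_lower_g, row$mean_upper_g), c(0.4, 0.9))

  # three hand-built individuals against a hand-computed average
  three <- tibble::tibble(
    participant_id = c("A", "B", "C"),
    gender = factor(c("female", "female", "male"), levels = c("female", "male")),
    age = c(25L, 34L, 25L), k = 1L, market_share = 0,
    lower_g = c(0.1, 0.2, 0.6), upper_g = c(0.3, 0.5, 1.0)
  )
  s3 <- suppressWarnings(summarize_reduction(three))
  tot <- dplyr::filter(s3, stratum == "total", age_band == "All")
  expect_equal(tot$mean_lower_g, (0.1 + 0.2 + 0.6) / 3)
  expect_equal(tot$mean_upper_g, (0.3 + 0.5 + 1.0) / 3)
  w <- dplyr::filter(s3, stratum == "women", age_band == "All")
  expect_equal(w$mean_lower_g, 0.15)

  # linearity of the mean: stratum means at share 0.6 are 0.4 x share-0 means
  both <- dplyr::bind_rows(
    three,
    dplyr::mutate(three, k = 3L, market_share = 0.6,
                  lower_g = lower_g * 0.4, upper_g = upper_g * 0.4)
  )
  sb <- suppressWarnings(summarize_reduction(both))
  t1 <- dplyr::filter(sb, stratum == "total", age_band == "All", k == 1)
  t3 <- dplyr::filter(sb, stratum == "total", age_band == "All", k == 3)
  expect_equal(t3$mean_lower_g, 0.4 * t1$mean_lower_g)
  expect_equal(t3$mean_upper_g, 0.4 * t1$mean_upper_g)
})

test_that("half-up rounding reproduces printed-table formatting", {
  expect_equal(round_half_up(4.95, 2), 4.95)
  expect_equal(round_half_up(0.368, 2), 0.37)
  expect_equal(round_half_up(0.0455, 3), 0.046)
  expect_equal(round_half_up(0.315, 2), 0.32) # base round() would give 0.31
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("rate table divides rounded grams by rounded intake", {
  intake <- tibble::tibble(
    stratum = "total", age_band = "All", n = 10L,
    mean_intake = 4.95, sd_intake = 1.91
  )
  grams <- tibble::tibble(
    stratum = "total", age_band = "All",
    k = c(1L, 2L, 4L), market_share = c(0, 0.3, 0.9), n = 10L,
    mean_lower_g = c(0.45, 0.31, 0.045), mean_upper_g = c(0.92, 0.64, 0.092)
  )
  rt <- reduction_rate_table(grams, intake)
  expect_equal(rt$rate_lower_pct, c(9.09, 6.26, 0.91))
  expect_equal(rt$rate_upper_pct, c(18.59, 12.93, 1.86))

  zero <- dplyr::mutate(grams, mean_lower_g = 0)
  expect_equal(reduction_rate_table(zero, intake)$rate_lower_pct, c(0, 0, 0))

  expect_error(
    reduction_rate_table(dplyr::mutate(grams, stratum = "women"), intake),
    class = "saltscen_validation_error"
  )
})

test_that("report files carry printed-precision cells", {
  fx <- random_fixture(n_people = 40, seed = 707)
  fit <- suppressWarnings(run_salt_scenarios(
    fx$participants, fx$diary, synthetic_prefix_overlay()
  ))
  dir <- withr::local_tempdir()
  paths <- format_tables(fit$intake_summary, fit$reduction_summary,
                         fit$rate_table, dir)
  expect_true(all(file.exists(paths)))

  t3 <- readr::read_tsv(paths[["table3"]], show_col_types = FALSE)
  # share-0.9 column prints 3 decimals, the others 2
  s4_cells <- t3[[grep("share_0.9", names(t3))]]
  expect_true(all(grepl("^[0-9]+\\.[0-9]{3}-[0-9]+\\.[0-9]{3}$", s4_cells)))
  s1_cells <- t3[[grep("share_0$", names(t3))]]
  expect_true(all(grepl("^[0-9]+\\.[0-9]{2}-[0-9]+\\.[0-9]{2}$", s1_cells)))

  t2 <- readr::read_tsv(paths[["table2"]], show_col_types = FALSE)
  expect_equal(nrow(dplyr::filter(t2, age_band == "All")), 3L)
})
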