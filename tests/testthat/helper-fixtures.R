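# shared fixture builders and brute-force oracles

make_participants <- function(ids, gender = "female", age = 34L,
                              n_diary_days = 4L) {
  validate_participants(tibble::tibble(
    participant_id = ids,
    gender = rep_len(gender, length(ids)),
    age = rep_len(age, length(ids)),
    n_diary_days = rep_len(n_diary_days, length(ids))
  ))
}

make_record <- function(participant_id, day = 1L, food_code = "14R",
                        main_group_code = 14L, amount_g = 100,
                        sodium_mg_per_100g = 700) {
  tibble::tibble(
    participant_id = participant_id, day = day, food_code = food_code,
    main_group_code = main_group_code, amount_g = amount_g,
    sodium_mg_per_100g = sodium_mg_per_100g
  )
}

# random diary fixture over a mix of matched and unmatched codes
random_fixture <- function(n_people = 20, seed = 101,
                           registry = synthetic_prefix_overlay()) {
  withr::with_seed(seed, {
    participants <- validate_participants(tibble::tibble(
      participant_id = sprintf("R%03d", seq_len(n_people)),
      gender = sample(c("female", "male"), n_people, replace = TRUE),
      age = sample(20:90, n_people, replace = TRUE),
      n_diary_days = sample(c(3L, 4L), n_people, replace = TRUE,
                            prob = c(0.3, 0.7))
    ))
    codes <- tibble::tibble(
      food_code = c("14A", "22B", "30C", "42A", "38B", "17A",
                    "500A", "515B", "520C", "533A", "541B", "556C",
                    "990A", "88X", "7A"),
      main_group_code = c(14L, 22L, 30L, 42L, 38L, 17L,
                          50L, 51L, 52L, 53L, 54L, 55L,
                          99L, 88L, 7L)
    )
    diary <- purrr::map(participants$participant_id, function(pid) {
      nd <- participants$n_diary_days[participants$participant_id == pid]
      n_rec <- sample(3:10, 1)
      idx <- sample(nrow(codes), n_rec, replace = TRUE)
      tibble::tibble(
        participant_id = pid,
        day = sample(seq_len(nd), n_rec, replace = TRUE),
        food_code = codes$food_code[idx],
        main_group_code = codes$main_group_code[idx],
        amount_g = stats::runif(n_rec, 5, 300),
        sodium_mg_per_100g = stats::runif(n_rec, 10, 3000)
      )
    }) |> dplyr::bind_rows()
    list(participants = participants,
         diary = validate_diary(diary, participants))
  })
}

# oracle: total reduction bounds computed record by record, bypassing the
# category grouping the pipeline uses
brute_force_reduction <- function(diary, participants, registry, scenarios) {
  rates <- dplyr::select(registry, "category_id", "lower_rate", "upper_rate")
  recs <- diary |>
    dplyr::mutate(
      category_id = match_category(diary$food_code, diary$main_group_code,
                                   registry),
      sodium_mg = amount_g * sodium_mg_per_100g / 100
    ) |>
    dplyr::left_join(rates, by = "category_id") |>
    dplyr::left_join(
      dplyr::select(participants, "participant_id", "n_diary_days"),
      by = "participant_id"
    )
  out <- list()
  for (i in seq_len(nrow(scenarios))) {
    m <- scenarios$market_share[i]
    per_rec <- recs |>
      dplyr::mutate(
        salt = sodium_mg * 2.54 / 1000 / n_diary_days,
        lo = ifelse(is.na(category_id), 0, salt * lower_rate * (1 - m)),
        up = ifelse(is.na(category_id), 0, salt * upper_rate * (1 - m))
      ) |>
      dplyr::summarise(lower_g = sum(lo), upper_g = sum(up),
                       .by = "participant_id")
    per_rec$k <- scenarios$k[i]
    per_rec$market_share <- m
    out[[i]] <- per_rec
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(participant_id, k)
}
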