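#' Published UK adult calibration targets: cohort and current salt intake
#'
#' Gender- and age-stratified participant counts and mean (SD) daily salt
#' intake for adults aged 20+ in the UK National Diet and Nutrition Survey
#' Rolling Programme 2016/2017–2018/2019, as published. These printed values
#' are inputs to this package: they are the default calibration targets of the
#' synthetic-cohort generator ([cohort_config()], [diet_config()]) and the
#' intake side of the printed-table reconstruction in
#' [reduction_rate_table()]. The underlying microdata (UK Data Service study
#' 6533) are not shipped and are not needed for any computation here.
#'
#' @return A tibble `stratum` (total/women/men), `age_band`, `n`,
#'   `mean_intake`, `sd_intake` (g/day).
#' @seealso [reference_reduction_g()]
#' @export
reference_intake <- function() {
  bands <- c(age_band_levels(), "All")
  tibble::tibble(
    stratum = factor(rep(c("total", "women", "men"), each = 8),
                     levels = c("total", "women", "men")),
    age_band = factor(rep(bands, 3), levels = bands),
    n = c(
      230L, 332L, 340L, 340L, 275L, 208L, 109L, 1834L,
      145L, 194L, 210L, 193L, 148L, 121L, 65L, 1076L,
      85L, 138L, 130L, 147L, 127L, 87L, 44L, 758L
    ),
    mean_intake = c(
      5.37, 5.39, 5.13, 4.80, 4.65, 4.36, 4.49, 4.95,
      4.81, 4.86, 4.63, 4.18, 4.19, 3.98, 4.13, 4.45,
      6.32, 6.14, 5.94, 5.62, 5.20, 4.89, 5.01, 5.66
    ),
    sd_intake = c(
      2.31, 2.13, 1.85, 1.78, 1.66, 1.46, 1.66, 1.91,
      1.91, 1.84, 1.51, 1.37, 1.34, 1.28, 1.50, 1.60,
      2.63, 2.27, 2.05, 1.92, 1.82, 1.52, 1.76, 2.09
    )
  )
}

#' Published UK adult calibration targets: mean salt reduction (g/day)
#'
#' The published gender- and age-stratified mean lower/upper salt-reduction
#' bounds (g/day) for the four market-share scenarios, at printed precision
#' (2 decimals; 3 decimals for the 90%-share scenario). Together with
#' [reference_intake()] these printed values reproduce the published
#' reduction-rate table through [reduction_rate_table()] — the exact,
#' desk-scale consistency check of the reporting conventions.
#'
#' @return A tibble `stratum`, `age_band`, `k`, `market_share`,
#'   `mean_lower_g`, `mean_upper_g`.
#' @export
reference_reduction_g <- function() {
  bands <- c(age_band_levels(), "All")
  # printed cells, scenario-major within stratum: lower then upper
  cells <- list(
    total = list(
      s1 = rbind(
        c(0.48, 0.98), c(0.47, 0.95), c(0.49, 1.01), c(0.42, 0.87),
        c(0.42, 0.90), c(0.39, 0.80), c(0.42, 0.85), c(0.45, 0.92)
      ),
      s2 = rbind(
        c(0.33, 0.69), c(0.33, 0.67), c(0.34, 0.71), c(0.29, 0.61),
        c(0.29, 0.63), c(0.27, 0.56), c(0.30, 0.60), c(0.31, 0.64)
      ),
      s3 = rbind(
        c(0.19, 0.39), c(0.19, 0.38), c(0.20, 0.40), c(0.17, 0.35),
        c(0.17, 0.36), c(0.16, 0.32), c(0.17, 0.34), c(0.18, 0.37)
      ),
      s4 = rbind(
        c(0.048, 0.098), c(0.047, 0.095), c(0.049, 0.100), c(0.042, 0.087),
        c(0.042, 0.090), c(0.039, 0.080), c(0.042, 0.085), c(0.045, 0.092)
      )
    ),
    women = list(
      s1 = rbind(
        c(0.43, 0.86), c(0.45, 0.88), c(0.44, 0.89), c(0.37, 0.75),
        c(0.40, 0.82), c(0.37, 0.70), c(0.37, 0.76), c(0.41, 0.82)
      ),
      s2 = rbind(
        c(0.30, 0.60), c(0.31, 0.62), c(0.31, 0.62), c(0.26, 0.52),
        c(0.28, 0.58), c(0.26, 0.49), c(0.26, 0.53), c(0.29, 0.57)
      ),
      s3 = rbind(
        c(0.17, 0.34), c(0.18, 0.35), c(0.18, 0.36), c(0.15, 0.30),
        c(0.16, 0.33), c(0.15, 0.28), c(0.15, 0.31), c(0.16, 0.33)
      ),
      s4 = rbind(
        c(0.043, 0.086), c(0.045, 0.088), c(0.044, 0.089), c(0.037, 0.075),
        c(0.040, 0.082), c(0.037, 0.070), c(0.037, 0.076), c(0.041, 0.082)
      )
    ),
    men = list(
      s1 = rbind(
        c(0.56, 1.20), c(0.50, 1.04), c(0.56, 1.20), c(0.49, 1.04),
        c(0.44, 0.98), c(0.43, 0.93), c(0.50, 0.98), c(0.50, 1.10)
      ),
      s2 = rbind(
        c(0.40, 0.84), c(0.35, 0.73), c(0.39, 0.84), c(0.34, 0.73),
        c(0.31, 0.69), c(0.30, 0.65), c(0.35, 0.69), c(0.35, 0.74)
      ),
      s3 = rbind(
        c(0.23, 0.48), c(0.20, 0.42), c(0.22, 0.48), c(0.20, 0.42),
        c(0.18, 0.39), c(0.17, 0.37), c(0.20, 0.39), c(0.20, 0.42)
      ),
      s4 = rbind(
        c(0.056, 0.120), c(0.050, 0.100), c(0.056, 0.120), c(0.049, 0.100),
        c(0.044, 0.098), c(0.043, 0.093), c(0.050, 0.098), c(0.050, 0.110)
      )
    )
  )
  shares <- c(0, 0.3, 0.6, 0.9)
  purrr::imap(cells, function(scen_list, stratum) {
    purrr::imap(scen_list, function(m, s_name) {
      k <- as.integer(sub("s", "", s_name))
      tibble::tibble(
        stratum = stratum, age_band = bands, k = k,
        market_share = shares[k],
        mean_lower_g = m[, 1], mean_upper_g = m[, 2]
      )
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      stratum = factor(.data$stratum, levels = c("total", "women", "men")),
      age_band = factor(.data$age_band, levels = bands)
    ) |>
    dplyr::arrange(.data$stratum, .data$k, .data$age_band)
}
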