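#' Plot a salt-scenario analysis
#'
#' @param object A `salt_scenarios` object from [run_salt_scenarios()].
#' @param type `"reduction"` (default): mean lower–upper reduction bounds in
#'   g/day by age band, faceted by gender stratum, coloured by scenario;
#'   `"rates"`: the same as percentages of current intake; `"intake"`:
#'   current mean intake with SD whiskers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.salt_scenarios <- function(object,
                                    type = c("reduction", "rates", "intake"),
                                    ...) {
  type <- match.arg(type)
  if (type == "intake") {
    d <- dplyr::filter(object$intake_summary, .data$age_band != "All")
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$age_band,
                                      y = .data$mean_intake)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::geom_errorbar(
          ggplot2::aes(ymin = .data$mean_intake - .data$sd_intake,
                       ymax = .data$mean_intake + .data$sd_intake),
          width = 0.25
        ) +
        ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
        ggplot2::labs(x = "age band", y = "mean salt intake (g/day)",
                      title = "Current daily salt intake") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
    )
  }
  d <- dplyr::filter(object$rate_table, .data$age_band != "All") |>
    dplyr::mutate(
      scenario = factor(sprintf("share %d%%",
                                round(.data$market_share * 100)),
                        levels = sprintf("share %d%%",
                                         round(sort(unique(
                                           .data$market_share)) * 100)))
    )
  if (type == "reduction") {
    aes_low <- "mean_lower_g"
    aes_up <- "mean_upper_g"
    ylab <- "salt reduction (g/day)"
    title <- "Achievable salt reduction by scenario"
  } else {
    aes_low <- "rate_lower_pct"
    aes_up <- "rate_upper_pct"
    ylab <- "salt reduction (% of current intake)"
    title <- "Achievable salt reduction rate by scenario"
  }
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$age_band, colour = .data$scenario)
  ) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data[[aes_low]], ymax = .data[[aes_up]]),
      position = ggplot2::position_dodge(width = 0.6), linewidth = 1.2
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::labs(x = "age band", y = ylab, colour = NULL, title = title,
                  subtitle = "bars span the lower-upper reduction-rate bounds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.salt_scenarios
#' @param x A `salt_scenarios` object.
#' @export
plot_reduction <- function(x, ...) {
  autoplot.salt_scenarios(x, type = "reduction", ...)
}

#' @rdname autoplot.salt_scenarios
#' @export
plot_reduction_rates <- function(x, ...) {
  autoplot.salt_scenarios(x, type = "rates", ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
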