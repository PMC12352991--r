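#' Plot per-age-group bias of each method
#'
#' Bars of mean DA − CA by integer age group, faceted by sex, one fill per
#' method. Total rows are dropped from the display.
#'
#' @param object a `dentage_bias` table from [bias_table()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dentage_bias <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$age_group != "total") |>
    select("sex", "age_group", "bias_becker", "bias_demirjian") |>
    pivot_longer(c("bias_becker", "bias_demirjian"),
                 names_to = "method", values_to = "bias",
                 names_prefix = "bias_") |>
    filter(!is.na(.data$bias))
  ggplot(df, aes(x = .data$age_group, y = .data$bias, fill = .data$method)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = 0, linetype = 2) +
    facet_wrap(~sex) +
    labs(
      x = "age group (floor of chronological age, years)",
      y = "mean DA - CA (years)", fill = NULL
    ) +
    theme_minimal()
}

#' Scatter of estimated dental age against chronological age
#'
#' One panel per method with the OLS fit and the identity line; the slope of
#' the fit against the identity is the usual visual check of method
#' calibration.
#'
#' @param estimates tibble from [estimate_cohort()].
#' @return A ggplot object.
#' @export
plot_agreement <- function(estimates) {
  df <- estimates |> filter(!is.na(.data$da_point))
  ggplot(df, aes(x = .data$ca_years, y = .data$da_point, colour = .data$sex)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "black") +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    facet_wrap(~method) +
    labs(x = "chronological age (years)", y = "estimated dental age (years)") +
    theme_minimal()
}

#' Dot-and-interval plot of an ICC panel
#'
#' @param object a `dentage_icc` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dentage_icc <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = paste(.data$form, .data$unit), y = .data$estimate)) +
    geom_pointrange(aes(ymin = .data$lower, ymax = .data$upper)) +
    coord_flip() +
    labs(x = NULL, y = "intraclass correlation") +
    theme_minimal()
}
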