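#' Intraclass correlation coefficients (Shrout–Fleiss panel)
#'
#' Computes all six classical ICC forms from the two-way ANOVA mean squares
#' of a complete subjects-by-raters matrix: one-way random (ICC1), two-way
#' random with absolute agreement (ICC2) and two-way mixed consistency
#' (ICC3), each for a single rating and for the average of the k ratings,
#' with F-based confidence intervals. Ratings in an agreement study come
#' from fixed, named examiners, so ICC3 single is the default display; the
#' full panel is always returned.
#'
#' @param data long tibble of ratings.
#' @param subject,rater,value names of the subject, rater (or session) and
#'   score columns (defaults `subject_id`, `rater_id`, `da_point`).
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return A `dentage_icc` tibble with one row per form: `form` (`ICC1`,
#'   `ICC2`, `ICC3`), `unit` (`single`/`average`), `estimate`, `lower`,
#'   `upper`, plus attributes `n_subjects`, `n_raters`.
#' @export
#' @examples
#' ratings <- tibble::tibble(
#'   subject_id = rep(1:6, 2),
#'   rater_id = rep(c("A", "B"), each = 6),
#'   da_point = c(9, 10, 11, 12, 13, 14, 9.5, 10.2, 10.9, 12.1, 12.8, 14.2)
#' )
#' icc(ratings)
icc <- function(data, subject = "subject_id", rater = "rater_id",
                value = "da_point", conf_level = 0.95) {
  stopifnot(is.data.frame(data))
  mat <- data |>
    select(all_of(c(subject, rater, value))) |>
    pivot_wider(names_from = all_of(rater), values_from = all_of(value)) |>
    select(-all_of(subject)) |>
    as.matrix()
  if (anyNA(mat)) abort("icc: rating matrix has missing cells (no imputation is done)")
  n <- nrow(mat)
  k <- ncol(mat)
  if (k < 2L) abort("icc needs at least 2 raters/sessions")
  if (n < 5L) abort("icc needs at least 5 subjects")

  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  jms <- ss_cols / (k - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  wms <- (ss_cols + ss_err) / (n * (k - 1))

  a <- 1 - conf_level
  # ICC(1): one-way random
  icc1 <- (bms - wms) / (bms + (k - 1) * wms)
  icc1k <- (bms - wms) / bms
  f1 <- bms / wms
  f1l <- f1 / qf(1 - a / 2, n - 1, n * (k - 1))
  f1u <- f1 * qf(1 - a / 2, n * (k - 1), n - 1)
  # ICC(3): two-way mixed, consistency
  icc3 <- (bms - ems) / (bms + (k - 1) * ems)
  icc3k <- (bms - ems) / bms
  f3 <- bms / ems
  f3l <- f3 / qf(1 - a / 2, n - 1, (n - 1) * (k - 1))
  f3u <- f3 * qf(1 - a / 2, (n - 1) * (k - 1), n - 1)
  # ICC(2): two-way random, absolute agreement (Satterthwaite df for the CI)
  icc2 <- (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
  icc2k <- (bms - ems) / (bms + (jms - ems) / n)
  fj <- jms / ems
  vn <- (k - 1) * (n - 1) * (k * icc2 * fj + n * (1 + (k - 1) * icc2) - k * icc2)^2
  vd <- (n - 1) * k^2 * icc2^2 * fj^2 + (n * (1 + (k - 1) * icc2) - k * icc2)^2
  v <- vn / vd
  f2l <- qf(1 - a / 2, n - 1, v)
  f2u <- qf(1 - a / 2, v, n - 1)
  l2 <- n * (bms - f2l * ems) / (f2l * (k * jms + (k * n - k - n) * ems) + n * bms)
  u2 <- n * (f2u * bms - ems) / (k * jms + (k * n - k - n) * ems + n * f2u * bms)
  step_up <- function(r) r * k / (1 + (k - 1) * r)

  out <- tibble(
    form = rep(c("ICC1", "ICC2", "ICC3"), each = 2),
    unit = rep(c("single", "average"), times = 3),
    estimate = c(icc1, icc1k, icc2, icc2k, icc3, icc3k),
    lower = c(
      (f1l - 1) / (f1l + k - 1), 1 - 1 / f1l,
      l2, step_up(l2),
      (f3l - 1) / (f3l + k - 1), 1 - 1 / f3l
    ),
    upper = c(
      (f1u - 1) / (f1u + k - 1), 1 - 1 / f1u,
      u2, step_up(u2),
      (f3u - 1) / (f3u + k - 1), 1 - 1 / f3u
    )
  )
  structure(
    out,
    class = c("dentage_icc", class(out)),
    n_subjects = n, n_raters = k, conf_level = conf_level,
    mean_squares = c(BMS = bms, JMS = jms, EMS = ems, WMS = wms)
  )
}

#' @export
print.dentage_icc <- function(x, digits = 3, ...) {
  cat(
    "Intraclass correlation (", attr(x, "n_subjects"), " subjects x ",
    attr(x, "n_raters"), " raters/sessions; default display: ICC3 single)\n",
    sep = ""
  )
  show <- as_tibble(x) |>
    mutate(across(c("estimate", "lower", "upper"), ~ round(.x, digits)))
  print(as.data.frame(show), row.names = FALSE)
  invisible(x)
}

#' @rdname icc
#' @param x a `dentage_icc` object.
#' @param ... unused.
#' @export
tidy.dentage_icc <- function(x, ...) {
  as_tibble(x)
}

#' @rdname icc
#' @export
glance.dentage_icc <- function(x, ...) {
  default <- as_tibble(x) |> filter(.data$form == "ICC3", .data$unit == "single")
  tibble(
    icc = default$estimate,
    lower = default$lower,
    upper = default$upper,
    form = "ICC3 single",
    n_subjects = attr(x, "n_subjects"),
    n_raters = attr(x, "n_raters")
  )
}

#' Intra- and inter-rater reliability panel for a rated cohort
#'
#' Reproduces the layout of a reliability study with two raters and two
#' sessions: intra-rater ICC per rater (sessions as the repeated factor) and
#' inter-rater ICC per session (raters as the repeated factor), for each
#' estimation method present.
#'
#' @param estimates tibble from [estimate_cohort()] on a cohort with several
#'   raters/sessions.
#' @param form which panel row to report (default `"ICC3"` single).
#' @return A tibble: `method`, `comparison` (`intra`/`inter`), `within`
#'   (the rater or session held fixed), `icc`, `lower`, `upper`.
#' @export
icc_panel <- function(estimates, form = "ICC3") {
  est <- estimates |> filter(!is.na(.data$da_point))
  pick <- function(x) {
    as_tibble(x) |> filter(.data$form == !!form, .data$unit == "single")
  }
  out <- list()
  for (m in unique(est$method)) {
    em <- est |> filter(.data$method == m)
    for (r in sort(unique(em$rater_id))) {
      sub <- em |> filter(.data$rater_id == r)
      if (dplyr::n_distinct(sub$session_id) >= 2) {
        res <- pick(icc(sub, rater = "session_id"))
        out <- c(out, list(tibble(
          method = m, comparison = "intra", within = r,
          icc = res$estimate, lower = res$lower, upper = res$upper
        )))
      }
    }
    for (s in sort(unique(em$session_id))) {
      sub <- em |> filter(.data$session_id == s)
      if (dplyr::n_distinct(sub$rater_id) >= 2) {
        res <- pick(icc(sub, rater = "rater_id"))
        out <- c(out, list(tibble(
          method = m, comparison = "inter", within = s,
          icc = res$estimate, lower = res$lower, upper = res$upper
        )))
      }
    }
  }
  list_rbind(out)
}
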