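#' Wilcoxon signed-rank test for paired differences
#'
#' Signed-rank test with midranks for tied absolute differences. For
#' `n <= 25` usable differences the two-sided p-value comes from the exact
#' null distribution of the positive-rank sum, enumerated by a
#' generating-function convolution that handles ties; above that, a normal
#' approximation with tie correction and (optionally) a continuity
#' correction is used. Zero differences are dropped before ranking by
#' default (Wilcoxon's original policy); `zero_policy = "pratt"` ranks them
#' first and then discards their ranks.
#'
#' @param differences numeric vector of paired differences (or `x`), NAs
#'   dropped.
#' @param y optional second sample; if given, differences = `differences - y`.
#' @param zero_policy `"drop"` (default) or `"pratt"`.
#' @param exact force exact (`TRUE`) or approximate (`FALSE`); default
#'   `NULL` picks exact for n <= 25.
#' @param correct apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return A one-row tibble: `statistic` (positive-rank sum W), `p_value`
#'   (two-sided), `n_used` (nonzero differences ranked), `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
wilcoxon_signed_rank <- function(differences, y = NULL,
                                 zero_policy = c("drop", "pratt"),
                                 exact = NULL, correct = TRUE) {
  zero_policy <- match.arg(zero_policy)
  d <- if (is.null(y)) differences else differences - y
  d <- d[!is.na(d)]
  if (length(d) == 0L) abort("no non-missing differences")
  if (all(d == 0)) {
    warn("all differences are zero; the test is degenerate")
    return(tibble(statistic = 0, p_value = 1, n_used = 0L, method = "degenerate"))
  }
  if (zero_policy == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    d <- d[keep]
    r <- r_all[keep]
  }
  n <- length(d)
  w <- sum(r[d > 0])
  use_exact <- exact %||% (n <= 25L)

  if (use_exact) {
    # exact null distribution of 2W via generating-function convolution;
    # doubling makes midranks (k + 0.5) integral
    r2 <- as.integer(round(2 * r))
    s <- sum(r2)
    f <- numeric(s + 1L)
    f[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(s + 1L - ri)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_lower <- sum(probs[seq_len(w2 + 1L)])
    p_upper <- sum(probs[seq(w2 + 1L, s + 1L)])
    p <- min(1, 2 * min(p_lower, p_upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- w - mu
    if (correct) z <- z - sign(z) * 0.5
    z <- z / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble(statistic = w, p_value = p, n_used = n, method = method)
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("pearson_r needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("degenerate input: zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Ordinary least-squares simple regression
#'
#' @param x predictor (chronological age in the comparison setting).
#' @param y response (a method's dental-age estimates).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `slope_se`,
#'   `n`.
#' @export
linreg <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("linreg needs at least 3 complete pairs")
  if (var(x) == 0) abort("degenerate input: constant x")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    slope_se = sm$coefficients["x", "Std. Error"],
    n = length(x)
  )
}

#' Test whether two methods share a regression slope on the same predictor
#'
#' Stacks the two responses, adds a method indicator and tests the
#' predictor-by-method interaction in `y ~ x * method`; a two-sided p-value
#' near 1 means the slopes are indistinguishable (an intercept-only offset
#' between methods does not register).
#'
#' @param x shared predictor.
#' @param y1,y2 the two methods' responses on the same subjects.
#' @return A one-row tibble: `p_value`, `slope1`, `slope2`,
#'   `slope_difference`, `n`.
#' @export
slope_equality_test <- function(x, y1, y2) {
  if (length(y1) != length(x) || length(y2) != length(x)) {
    abort("x, y1 and y2 must have the same length")
  }
  keep <- !is.na(x) & !is.na(y1) & !is.na(y2)
  x <- x[keep]; y1 <- y1[keep]; y2 <- y2[keep]
  if (length(x) < 3L) abort("slope_equality_test needs at least 3 complete triples")
  n_pairs <- length(x)
  df <- tibble(
    y = c(y1, y2),
    x = rep(x, 2),
    m = factor(rep(c("m1", "m2"), each = n_pairs))
  )
  fit <- lm(y ~ x * m, data = df)
  sm <- suppressWarnings(summary(fit))$coefficients
  f1 <- linreg(x, y1)
  f2 <- linreg(x, y2)
  tibble(
    p_value = sm["x:mm2", "Pr(>|t|)"],
    slope1 = f1$slope,
    slope2 = f2$slope,
    slope_difference = f2$slope - f1$slope,
    n = length(x)
  )
}

#' Age-by-sex bias table for dental-age methods
#'
#' Stratifies per-subject estimates by integer age group (floor of
#' chronological age) and sex, reporting per-stratum n, mean (sample SD,
#' n−1 denominator) of CA and of each method's DA, the signed biases
#' DA − CA, the between-method difference, and per-stratum signed-rank
#' p-values. A `total` row per sex and an overall `all`/`total` row are
#' appended. The difference columns are exact means of per-subject
#' differences, which for complete strata equal the difference of the mean
#' columns at full precision.
#'
#' @param estimates tibble from [estimate_cohort()] (one row per subject and
#'   method; restrict to a single rater/session first if several are
#'   present).
#' @return A `dentage_bias` tibble with columns `sex`, `age_group`, `n`,
#'   `ca_mean`, `ca_sd`, `becker_mean`, `becker_sd`, `demirjian_mean`,
#'   `demirjian_sd`, `bias_becker`, `bias_demirjian`,
#'   `demirjian_minus_becker`, `p_becker`, `p_demirjian`, `p_methods`.
#' @export
bias_table <- function(estimates) {
  if (dplyr::n_distinct(paste(estimates$rater_id %||% "R1", estimates$session_id %||% "S1")) > 1) {
    warn("bias_table: several rater/session combinations present; they are pooled")
  }
  wide <- estimates |>
    select("subject_id", "sex", "ca_years", "method", "da_point") |>
    pivot_wider(names_from = "method", values_from = "da_point")
  for (m in c("becker", "demirjian")) {
    if (!m %in% names(wide)) wide[[m]] <- NA_real_
  }
  wide <- wide |> mutate(age_group = as.character(floor(.data$ca_years)))

  ages <- as.character(seq(floor(min(wide$ca_years)), floor(max(wide$ca_years))))
  frame <- bind_rows(
    tidyr::expand_grid(sex = sort(unique(wide$sex)), age_group = ages),
    tibble(sex = sort(unique(wide$sex)), age_group = "total"),
    tibble(sex = "all", age_group = "total")
  )

  stratum_stats <- function(sx, ag) {
    rows <- wide
    if (sx != "all") rows <- rows |> filter(.data$sex == sx)
    if (ag != "total") rows <- rows |> filter(.data$age_group == ag)
    n <- nrow(rows)
    sd_or_na <- function(v) if (sum(!is.na(v)) >= 2) sd(v, na.rm = TRUE) else NA_real_
    safe_p <- function(d) {
      d <- d[!is.na(d)]
      if (length(d) < 1 || all(d == 0)) return(NA_real_)
      suppressWarnings(wilcoxon_signed_rank(d)$p_value)
    }
    mean_or_na <- function(v) if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
    tibble(
      sex = sx, age_group = ag, n = n,
      ca_mean = mean_or_na(rows$ca_years), ca_sd = sd_or_na(rows$ca_years),
      becker_mean = mean_or_na(rows$becker), becker_sd = sd_or_na(rows$becker),
      demirjian_mean = mean_or_na(rows$demirjian), demirjian_sd = sd_or_na(rows$demirjian),
      bias_becker = mean_or_na(rows$becker - rows$ca_years),
      bias_demirjian = mean_or_na(rows$demirjian - rows$ca_years),
      demirjian_minus_becker = mean_or_na(rows$demirjian - rows$becker),
      p_becker = safe_p(rows$becker - rows$ca_years),
      p_demirjian = safe_p(rows$demirjian - rows$ca_years),
      p_methods = safe_p(rows$demirjian - rows$becker)
    )
  }

  out <- pmap(frame, function(sex, age_group) stratum_stats(sex, age_group)) |>
    list_rbind()
  class(out) <- c("dentage_bias", class(out))
  out
}

#' @export
print.dentage_bias <- function(x, digits = 3, ...) {
  cat("Dental-age bias by age group and sex (DA - CA in years)\n\n")
  show <- as_tibble(x) |>
    mutate(
      across(c("ca_mean", "becker_mean", "demirjian_mean"), ~ round(.x, digits)),
      across(c("bias_becker", "bias_demirjian", "demirjian_minus_becker"), ~ round(.x, digits)),
      p_becker = format_p(.data$p_becker),
      p_demirjian = format_p(.data$p_demirjian),
      p_methods = format_p(.data$p_methods)
    ) |>
    select(
      "sex", "age_group", "n", "ca_mean", "becker_mean", "demirjian_mean",
      "bias_becker", "bias_demirjian", "demirjian_minus_becker",
      "p_becker", "p_demirjian", "p_methods"
    )
  print(as.data.frame(show), row.names = FALSE)
  invisible(x)
}

#' Correlation and regression comparison of two methods against CA
#'
#' For each sex and overall: Pearson r of each method's DA with CA, OLS
#' slopes, the slope-equality p-value, and the between-method correlation.
#'
#' @inheritParams bias_table
#' @return A tibble with one row per group (`F`, `M`, `all`).
#' @export
compare_methods <- function(estimates) {
  wide <- estimates |>
    select("subject_id", "sex", "ca_years", "method", "da_point") |>
    pivot_wider(names_from = "method", values_from = "da_point") |>
    filter(!is.na(.data$becker), !is.na(.data$demirjian))
  one <- function(rows, label) {
    tibble(
      group = label,
      n = nrow(rows),
      r_becker = pearson_r(rows$ca_years, rows$becker)$r,
      r_demirjian = pearson_r(rows$ca_years, rows$demirjian)$r,
      r_between = pearson_r(rows$becker, rows$demirjian)$r,
      slope_becker = linreg(rows$ca_years, rows$becker)$slope,
      slope_demirjian = linreg(rows$ca_years, rows$demirjian)$slope,
      r2_becker = linreg(rows$ca_years, rows$becker)$r_squared,
      r2_demirjian = linreg(rows$ca_years, rows$demirjian)$r_squared,
      p_slope_equality = slope_equality_test(rows$ca_years, rows$becker, rows$demirjian)$p_value
    )
  }
  bind_rows(
    one(wide, "all"),
    wide |> group_by(.data$sex) |> group_map(~ one(.x, .y$sex)) |> list_rbind()
  )
}
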