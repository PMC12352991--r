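#' A synthetic maturity table for the seven-tooth staging method
#'
#' The seven-tooth method stages the left mandibular permanent teeth (31–37)
#' into stages A–H, sums sex-specific self-weighted scores into a maturity
#' score and converts that score to a dental age on a sex-specific curve.
#' The published numeric tables are licensed reference material that this
#' package does not reproduce; this function returns a clearly synthetic
#' table with the same structure and invariants (scores non-decreasing A→H,
#' all-H total of 100, strictly increasing conversion knots) so the engine
#' can be exercised and tested. Supply real population tables through
#' [load_maturity_table()] for substantive use.
#'
#' @return A `maturity_table` object: a list with tibbles `scores`
#'   (`sex`, `tooth_fdi`, `stage`, `score`) and `conversion`
#'   (`sex`, `maturity_score`, `dental_age`).
#' @export
demirjian_table <- function() {
  teeth <- paste0("3", 1:7)
  max_score <- c(`31` = 10, `32` = 10, `33` = 12, `34` = 14, `35` = 16, `36` = 18, `37` = 20)
  frac <- list(
    M = c(UNFORMED = 0, A = 0.10, B = 0.20, C = 0.30, D = 0.45, E = 0.60, F = 0.75, G = 0.90, H = 1),
    F = c(UNFORMED = 0, A = 0.12, B = 0.22, C = 0.33, D = 0.48, E = 0.63, F = 0.78, G = 0.92, H = 1)
  )
  scores <- purrr::map(c("F", "M"), function(sx) {
    tidyr::expand_grid(sex = sx, tooth_fdi = teeth, stage = STAGE_LEVELS) |>
      mutate(score = unname(max_score[.data$tooth_fdi] * frac[[sx]][.data$stage]))
  }) |> list_rbind()
  knots <- seq(0, 100, by = 10)
  age_m <- c(3.0, 5.0, 6.5, 7.8, 8.8, 9.8, 10.8, 11.8, 13.0, 14.4, 16.0)
  age_f <- c(2.8, 4.7, 6.2, 7.5, 8.5, 9.5, 10.5, 11.5, 12.7, 14.1, 15.8)
  conversion <- bind_rows(
    tibble(sex = "F", maturity_score = knots, dental_age = age_f),
    tibble(sex = "M", maturity_score = knots, dental_age = age_m)
  )
  new_maturity_table(scores, conversion)
}

new_maturity_table <- function(scores, conversion) {
  tab <- structure(
    list(scores = as_tibble(scores), conversion = as_tibble(conversion)),
    class = "maturity_table"
  )
  validate_maturity_table(tab)
  tab
}

#' @export
print.maturity_table <- function(x, ...) {
  cat("<maturity_table>\n")
  cat("  scores:    ", nrow(x$scores), " rows (",
      paste(sort(unique(x$scores$sex)), collapse = "/"), "; teeth ",
      paste(range(x$scores$tooth_fdi), collapse = "-"), ")\n", sep = "")
  cat("  conversion:", nrow(x$conversion), "knots\n")
  invisible(x)
}

validate_maturity_table <- function(tab) {
  scores <- tab$scores
  conversion <- tab$conversion
  for (sx in c("F", "M")) {
    if (!sx %in% scores$sex) abort(paste0("maturity table: missing score block for sex ", sx))
    if (!sx %in% conversion$sex) abort(paste0("maturity table: missing conversion curve for sex ", sx))
  }
  teeth <- paste0("3", 1:7)
  blocks <- scores |> filter(.data$sex %in% c("F", "M"))
  for (sx in c("F", "M")) {
    for (tt in teeth) {
      s <- blocks |> filter(.data$sex == sx, .data$tooth_fdi == tt)
      if (!all(STAGE_LEVELS %in% s$stage)) {
        abort(paste0("maturity table: sex ", sx, " tooth ", tt, " is missing stages"))
      }
      v <- s$score[match(STAGE_LEVELS, s$stage)]
      if (any(is.na(v))) abort(paste0("maturity table: NA score for tooth ", tt, " sex ", sx))
      if (any(diff(v) < 0)) {
        bad <- STAGE_LEVELS[which(diff(v) < 0)[1] + 1L]
        abort(paste0(
          "maturity table: scores must be non-decreasing across stages; tooth ", tt,
          " sex ", sx, " decreases at stage ", bad
        ))
      }
    }
    total_h <- blocks |>
      filter(.data$sex == sx, .data$stage == "H") |>
      pull(.data$score) |>
      sum()
    if (total_h > 100 + 1e-8) {
      abort(paste0("maturity table: all-H total for sex ", sx, " exceeds 100 (", total_h, ")"))
    }
    knots <- conversion |> filter(.data$sex == sx) |> arrange(.data$maturity_score)
    if (nrow(knots) < 2) abort(paste0("maturity table: conversion curve for sex ", sx, " needs >= 2 knots"))
    if (any(diff(knots$maturity_score) <= 0) || any(diff(knots$dental_age) <= 0)) {
      abort(paste0(
        "maturity table: conversion knots for sex ", sx,
        " must be strictly increasing in score and age"
      ))
    }
  }
  invisible(tab)
}

#' Read a maturity table from CSV
#'
#' One file holds both blocks, distinguished by a `block` column:
#' `block = "score"` rows carry `sex`, `tooth_fdi`, `stage`, `score`;
#' `block = "conversion"` rows carry `sex`, `maturity_score`, `dental_age`.
#' All structural invariants are enforced at load time.
#'
#' @param path CSV file path.
#' @return A validated `maturity_table`.
#' @export
load_maturity_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("block", "sex", "tooth_fdi", "stage", "score", "maturity_score", "dental_age")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0(
      "maturity table file is missing column(s): ", paste(missing, collapse = ", "),
      "; expected schema: ", paste(needed, collapse = ", ")
    ))
  }
  scores <- raw |>
    filter(.data$block == "score") |>
    mutate(tooth_fdi = as.character(.data$tooth_fdi)) |>
    select("sex", "tooth_fdi", "stage", "score")
  conversion <- raw |>
    filter(.data$block == "conversion") |>
    select("sex", "maturity_score", "dental_age")
  new_maturity_table(scores, conversion)
}

#' Write a maturity table to the single-file CSV schema
#'
#' @param table a `maturity_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_maturity_table <- function(table, path) {
  stopifnot(inherits(table, "maturity_table"))
  out <- bind_rows(
    table$scores |> mutate(block = "score", maturity_score = NA_real_, dental_age = NA_real_),
    table$conversion |>
      mutate(block = "conversion", tooth_fdi = NA_character_, stage = NA_character_, score = NA_real_)
  ) |>
    select("block", "sex", "tooth_fdi", "stage", "score", "maturity_score", "dental_age")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_stage_records <- function(stages) {
  stopifnot(is.data.frame(stages))
  needed <- c("tooth_fdi", "stage")
  missing <- setdiff(needed, names(stages))
  if (length(missing) > 0) {
    abort(paste0("stage records need column(s): ", paste(missing, collapse = ", ")))
  }
  teeth <- paste0("3", 1:7)
  found <- stages |> filter(!is.na(.data$stage))
  if (!setequal(intersect(found$tooth_fdi, teeth), teeth) || anyDuplicated(found$tooth_fdi) > 0) {
    abort("the seven-tooth method requires a stage for each of teeth 31-37 (no substitution)")
  }
  bad <- !found$stage %in% STAGE_LEVELS
  if (any(bad)) {
    abort(paste0("unknown stage(s): ", paste(unique(found$stage[bad]), collapse = ", ")))
  }
  found |> filter(.data$tooth_fdi %in% teeth)
}

#' Summed maturity score for one subject
#'
#' @param stages data frame with `tooth_fdi`, `stage` covering all of
#'   teeth 31–37.
#' @param sex `"F"` or `"M"`.
#' @param table a `maturity_table`.
#' @return The summed score (scalar).
#' @export
#' @examples
#' stages <- tibble::tibble(tooth_fdi = paste0("3", 1:7), stage = "H")
#' maturity_score(stages, "F", demirjian_table())
maturity_score <- function(stages, sex, table = demirjian_table()) {
  stopifnot(inherits(table, "maturity_table"), sex %in% c("F", "M"))
  stages <- validate_stage_records(stages)
  joined <- stages |>
    inner_join(table$scores |> filter(.data$sex == !!sex), by = c("tooth_fdi", "stage"))
  if (nrow(joined) != 7L) {
    abort("stage lookup failed: stage/tooth combination absent from the maturity table")
  }
  sum(joined$score)
}

#' Estimate dental age from seven-tooth maturity staging
#'
#' Converts the summed maturity score to a dental age by piecewise-linear
#' interpolation on the sex-specific conversion curve. Scores outside the
#' curve's support are clamped to the nearest endpoint and flagged
#' `low_confidence`. This method yields a point (low = point = high).
#'
#' @inheritParams maturity_score
#' @return A one-row tibble: `method`, `da_point`, `da_low`, `da_high`,
#'   `maturity_score`, `flags`.
#' @export
#' @examples
#' stages <- tibble::tibble(tooth_fdi = paste0("3", 1:7), stage = "F")
#' estimate_demirjian(stages, "M")
estimate_demirjian <- function(stages, sex, table = demirjian_table()) {
  score <- maturity_score(stages, sex, table)
  knots <- table$conversion |>
    filter(.data$sex == !!sex) |>
    arrange(.data$maturity_score)
  flags <- character(0)
  if (score < min(knots$maturity_score) || score > max(knots$maturity_score)) {
    flags <- "low_confidence"
  }
  da <- stats::approx(
    knots$maturity_score, knots$dental_age,
    xout = score, rule = 2, ties = "ordered"
  )$y
  tibble(
    method = "demirjian",
    da_point = da,
    da_low = da,
    da_high = da,
    maturity_score = score,
    flags = flags_chr(flags)
  )
}
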