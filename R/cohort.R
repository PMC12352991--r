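#' Read a cohort file (long per-tooth format)
#'
#' One row per tooth observation. Required columns: `subject_id`, `sex`
#' (`F`/`M`), `tooth_fdi`, `apex_status` (`closed`/`open`/`unassessable`;
#' blank is read as unassessable). Chronological age comes either from a
#' `ca_years` decimal column or from `birth_date`/`exam_date` columns
#' (decimal years as days/365.25). Optional columns: `rater_id` (default
#' `"R1"`), `session_id` (default `"S1"`), `root_fraction` in \[0, 1\],
#' `demirjian_stage` (`UNFORMED`/`A`–`H`). Teeth absent from a subject's rows
#' are treated as unassessable downstream — absence of evidence is not an
#' open apex. Third molars load but are never consumed by either estimator.
#'
#' @param path CSV path (comma-separated, UTF-8, `.` decimal).
#' @param plausible_age two-element numeric window; chronological ages
#'   outside it raise a warning, not an error.
#' @return A validated tibble with columns `subject_id`, `sex`, `ca_years`,
#'   `rater_id`, `session_id`, `tooth_fdi`, `apex_status`, `root_fraction`,
#'   `demirjian_stage`.
#' @export
read_cohort <- function(path, plausible_age = c(3, 25)) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0L) abort(paste0("cohort file is empty: ", path))
  accepted <- c(
    "subject_id", "sex", "ca_years", "birth_date", "exam_date", "rater_id",
    "session_id", "tooth_fdi", "apex_status", "root_fraction", "demirjian_stage"
  )
  unknown <- setdiff(names(raw), accepted)
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown cohort column(s): ", paste(unknown, collapse = ", "),
      "; accepted schema: ", paste(accepted, collapse = ", ")
    ))
  }
  required <- c("subject_id", "sex", "tooth_fdi", "apex_status")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("cohort file is missing column(s): ", paste(missing, collapse = ", ")))
  }
  has_ca <- "ca_years" %in% names(raw)
  has_dates <- all(c("birth_date", "exam_date") %in% names(raw))
  if (!has_ca && !has_dates) {
    abort("cohort file needs either a ca_years column or birth_date + exam_date columns")
  }
  cohort <- raw |>
    mutate(
      row = dplyr::row_number() + 1L,  # header is line 1
      rater_id = if ("rater_id" %in% names(raw)) coalesce(.data$rater_id, "R1") else "R1",
      session_id = if ("session_id" %in% names(raw)) coalesce(.data$session_id, "S1") else "S1",
      root_fraction = if ("root_fraction" %in% names(raw)) as.numeric(.data$root_fraction) else NA_real_,
      demirjian_stage = if ("demirjian_stage" %in% names(raw)) .data$demirjian_stage else NA_character_,
      apex_status = coalesce(.data$apex_status, "unassessable")
    )
  if (has_ca) {
    cohort$ca_years <- as.numeric(cohort$ca_years)
  } else {
    bd <- as.Date(cohort$birth_date)
    xd <- as.Date(cohort$exam_date)
    cohort$ca_years <- as.numeric(xd - bd) / 365.25
  }
  validate_cohort(
    cohort |> select(
      "subject_id", "sex", "ca_years", "rater_id", "session_id",
      "tooth_fdi", "apex_status", "root_fraction", "demirjian_stage", "row"
    ),
    plausible_age = plausible_age,
    source = path
  ) |>
    select(-"row")
}

#' Validate a cohort tibble
#'
#' Checks the invariants [read_cohort()] promises: valid FDI codes, valid
#' status and stage labels, one chronological age per
#' (subject, rater, session), no duplicated tooth within that key, root
#' fractions in \[0, 1\] and consistent with closed apices. Ages outside the
#' plausibility window warn; everything else errors.
#'
#' @param cohort tibble in the [read_cohort()] shape.
#' @inheritParams read_cohort
#' @param source label used in messages (file path or "cohort").
#' @return The cohort, invisibly amended (invalid-free), as a tibble.
#' @export
validate_cohort <- function(cohort, plausible_age = c(3, 25), source = "cohort") {
  loc <- function(rows) {
    if ("row" %in% names(cohort)) paste0(" (line ", paste(head(rows, 5), collapse = ", "), ")") else ""
  }
  if (any(is.na(cohort$ca_years) | cohort$ca_years <= 0)) {
    bad <- which(is.na(cohort$ca_years) | cohort$ca_years <= 0)
    abort(paste0(source, ": chronological age must be a positive number", loc(cohort$row[bad])))
  }
  if (!all(cohort$sex %in% c("F", "M"))) {
    abort(paste0(source, ": sex must be F or M"))
  }
  parse_fdi(cohort$tooth_fdi)
  validate_apex_records(cohort)
  bad_stage <- !is.na(cohort$demirjian_stage) & !cohort$demirjian_stage %in% STAGE_LEVELS
  if (any(bad_stage)) {
    abort(paste0(
      source, ": unknown demirjian_stage value(s): ",
      paste(unique(cohort$demirjian_stage[bad_stage]), collapse = ", ")
    ))
  }
  dup <- cohort |>
    count(.data$subject_id, .data$rater_id, .data$session_id, .data$tooth_fdi) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      source, ": duplicated tooth observation for (subject, rater, session): ",
      paste(utils::head(paste(dup$subject_id, dup$rater_id, dup$session_id, dup$tooth_fdi, sep = "/"), 5),
            collapse = "; ")
    ))
  }
  multi_ca <- cohort |>
    group_by(.data$subject_id, .data$rater_id, .data$session_id) |>
    summarise(n_ca = dplyr::n_distinct(.data$ca_years), .groups = "drop") |>
    filter(.data$n_ca > 1)
  if (nrow(multi_ca) > 0) {
    abort(paste0(
      source, ": conflicting chronological ages within (subject, rater, session): ",
      paste(head(multi_ca$subject_id, 5), collapse = ", ")
    ))
  }
  outside <- cohort$ca_years < plausible_age[1] | cohort$ca_years > plausible_age[2]
  if (any(outside)) {
    warn(paste0(
      source, ": ", dplyr::n_distinct(cohort$subject_id[outside]),
      " subject(s) with chronological age outside the plausibility window [",
      plausible_age[1], ", ", plausible_age[2], "]"
    ))
  }
  third <- parse_fdi(cohort$tooth_fdi)$position == 8L
  if (any(third)) {
    warn(paste0(
      source, ": third molar observations present (",
      paste(unique(cohort$tooth_fdi[third]), collapse = ", "),
      "); third molars are ignored by both estimators"
    ))
  }
  invisible(as_tibble(cohort))
}

#' Write per-subject dental-age estimates to CSV
#'
#' @param estimates non-empty tibble of estimates as produced by
#'   [estimate_cohort()].
#' @param path output CSV path.
#' @param digits decimal precision preserved on round-trip (default 9).
#' @return `path`, invisibly.
#' @export
write_results <- function(estimates, path, digits = 9) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0L) {
    abort("no estimates to write")
  }
  out <- estimates |>
    mutate(across(c("da_point", "da_low", "da_high"), ~ round(.x, digits)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path CSV path.
#' @return tibble of estimates.
#' @export
read_results <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      sex = readr::col_character(),
      method = readr::col_character(),
      flags = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  ) |>
    mutate(flags = coalesce(.data$flags, ""))
}
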