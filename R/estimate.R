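#' Estimate dental age for every subject in a cohort
#'
#' Runs one or both estimators on each (subject, rater, session) row-group of
#' a long cohort table. A subject whose records cannot support a method
#' (no assessable apex, missing root fractions below the ladder floor, or an
#' incomplete seven-tooth staging) yields a row with `NA` estimates and the
#' `incomplete_data` flag rather than aborting the whole cohort. The walk is
#' vectorised across subjects; results are identical to calling
#' [estimate_becker()] / [estimate_demirjian()] subject by subject.
#'
#' @param cohort long cohort tibble, see [read_cohort()].
#' @param method `"both"` (default), `"becker"` or `"demirjian"`.
#' @param table maturity table for the staging method.
#' @param ladder apexification ladder, see [becker_ladder()].
#' @param anchors sub-nine root anchors, see [subnine_anchors()].
#' @param point range-collapse rule passed to [estimate_becker()].
#' @return A tibble with one row per (subject, rater, session, method):
#'   `subject_id`, `sex`, `ca_years`, `rater_id`, `session_id`, `method`,
#'   `da_point`, `da_low`, `da_high`, `flags`.
#' @export
#' @examples
#' cohort <- simulate_cohort(age_sex_design(c(10, 12), c(2, 2), c(2, 2)), seed = 1)
#' estimate_cohort(cohort)
estimate_cohort <- function(cohort,
                            method = c("both", "becker", "demirjian"),
                            table = demirjian_table(),
                            ladder = becker_ladder(),
                            anchors = subnine_anchors(),
                            point = c("midpoint", "low", "high")) {
  method <- match.arg(method)
  point <- match.arg(point)
  methods <- if (method == "both") c("becker", "demirjian") else method

  keys <- cohort |>
    distinct(.data$subject_id, .data$sex, .data$ca_years, .data$rater_id, .data$session_id) |>
    mutate(.key = dplyr::row_number())
  keyed <- cohort |>
    left_join(keys, by = c("subject_id", "sex", "ca_years", "rater_id", "session_id"))

  out <- list()
  if ("becker" %in% methods) {
    out <- c(out, list(becker_cohort(keyed, keys, ladder, anchors, point)))
  }
  if ("demirjian" %in% methods) {
    out <- c(out, list(demirjian_cohort(keyed, keys, table)))
  }
  list_rbind(out) |>
    arrange(.data$.key, .data$method) |>
    select(
      "subject_id", "sex", "ca_years", "rater_id", "session_id",
      "method", "da_point", "da_low", "da_high", "flags"
    )
}

# vectorised ladder walk over all subjects at once
becker_cohort <- function(keyed, keys, ladder, anchors, point) {
  groups <- ladder_groups(ladder)
  n_groups <- nrow(groups)
  assessed <- ladder |> filter(!.data$excluded) |> select("tooth_fdi", "group")

  st <- keyed |>
    inner_join(assessed, by = "tooth_fdi") |>
    group_by(.data$.key, .data$group) |>
    summarise(
      any_open = any(.data$apex_status == "open"),
      any_closed = any(.data$apex_status == "closed"),
      .groups = "drop"
    )
  # subjects x groups status matrices; groups without assessable members stay unknown
  open_m <- matrix(FALSE, nrow(keys), n_groups)
  closed_m <- matrix(FALSE, nrow(keys), n_groups)
  idx <- cbind(st$.key, st$group)
  open_m[idx] <- st$any_open
  closed_m[idx] <- st$any_closed & !st$any_open

  walk_one <- function(i) {
    status <- ifelse(open_m[i, ], "open", ifelse(closed_m[i, ], "closed", "unknown"))
    becker_walk(status)
  }
  walks <- purrr::map(seq_len(nrow(keys)), walk_one)
  k <- vapply(walks, function(w) w$k, integer(1))
  walk_flags <- vapply(walks, function(w) flags_chr(w$flags), character(1))
  has_assessable <- rowSums(open_m | closed_m) > 0

  res <- keys |>
    mutate(
      method = "becker",
      da_low = ifelse(k > 0, groups$da_low[pmax(k, 1L)], NA_real_),
      da_high = ifelse(k > 0, groups$da_high[pmax(k, 1L)], NA_real_),
      da_point = collapse_range(.data$da_low, .data$da_high, point),
      flags = walk_flags
    )

  # ladder floor not reached: interpolate root fractions (sub-nine path)
  floor_keys <- keys$.key[k == 0 & has_assessable]
  if (length(floor_keys) > 0) {
    contrib <- keyed |>
      filter(.data$.key %in% floor_keys, .data$apex_status == "open", !is.na(.data$root_fraction)) |>
      inner_join(anchors, by = "tooth_fdi") |>
      group_by(.data$.key) |>
      summarise(
        pt = mean(.data$root_start_age + .data$root_fraction * (.data$apex_age - .data$root_start_age)),
        .groups = "drop"
      )
    m <- match(contrib$.key, res$.key)
    res$da_point[m] <- contrib$pt
    res$da_low[m] <- contrib$pt
    res$da_high[m] <- contrib$pt
    res$flags[m] <- vapply(seq_along(m), function(j) {
      flags_chr(c(
        "low_confidence",
        if (contrib$pt[j] < 9) "sub_nine",
        strsplit(res$flags[m[j]], ",")[[1]][
          strsplit(res$flags[m[j]], ",")[[1]] == "inconsistent_sequence"
        ]
      ))
    }, character(1))
  }

  unresolved <- is.na(res$da_point)
  res$flags[unresolved] <- "incomplete_data"
  res$flags[!unresolved & res$da_high < 9 & k > 0] <- vapply(
    which(!unresolved & res$da_high < 9 & k > 0),
    function(i) flags_chr(c(strsplit(res$flags[i], ",")[[1]], "sub_nine")),
    character(1)
  )
  res
}

demirjian_cohort <- function(keyed, keys, table) {
  teeth <- paste0("3", 1:7)
  staged <- keyed |>
    filter(.data$tooth_fdi %in% teeth, !is.na(.data$demirjian_stage)) |>
    distinct(.data$.key, .data$sex, .data$tooth_fdi, .keep_all = TRUE) |>
    inner_join(table$scores, by = c("sex", "tooth_fdi", demirjian_stage = "stage"),
               relationship = "many-to-one")
  sums <- staged |>
    group_by(.data$.key) |>
    summarise(n_teeth = dplyr::n(), score = sum(.data$score), .groups = "drop") |>
    filter(.data$n_teeth == 7L)

  res <- keys |>
    mutate(
      method = "demirjian",
      score = sums$score[match(.data$.key, sums$.key)],
      da_point = NA_real_, flags = ""
    )
  for (sx in c("F", "M")) {
    knots <- table$conversion |> filter(.data$sex == sx) |> arrange(.data$maturity_score)
    rows <- which(res$sex == sx & !is.na(res$score))
    if (length(rows) == 0) next
    res$da_point[rows] <- stats::approx(
      knots$maturity_score, knots$dental_age,
      xout = res$score[rows], rule = 2, ties = "ordered"
    )$y
    clamped <- res$score[rows] < min(knots$maturity_score) |
      res$score[rows] > max(knots$maturity_score)
    res$flags[rows[clamped]] <- "low_confidence"
  }
  res$flags[is.na(res$da_point)] <- "incomplete_data"
  res |>
    mutate(da_low = .data$da_point, da_high = .data$da_point) |>
    select(-"score")
}
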