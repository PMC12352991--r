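#' The stepwise apexification ladder
#'
#' Tooth groups ordered by eruption timing, each carrying the dental age (DA)
#' read when that group is the last one whose root apices are all closed.
#' Two groups with highly variable development — the maxillary lateral
#' incisors and the mandibular second premolars — are excluded from the
#' diagnostic walk by default.
#'
#' @param include_maxillary_laterals include teeth 12/22 as an assessed rung
#'   (DA 10.5–11) instead of excluding them. The mandibular second premolars
#'   are always excluded (no DA value is defined for them).
#' @return A tibble with one row per tooth: `group` (ordinal index among the
#'   assessed rungs, `NA` for excluded teeth), `step` (position in the
#'   stepwise procedure), `label`, `tooth_fdi`, `da_low`, `da_high`,
#'   `excluded`. Assessed rungs are strictly increasing in `da_low`.
#' @export
#' @examples
#' becker_ladder()
#' becker_ladder(include_maxillary_laterals = TRUE)
becker_ladder <- function(include_maxillary_laterals = FALSE) {
  base <- tibble(
    step = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
    label = c(
      "mandibular central incisors",
      "first permanent molars",
      "mandibular lateral incisors",
      "maxillary central incisors",
      "maxillary lateral incisors",
      "mandibular canines and first premolars",
      "maxillary first premolars",
      "mandibular second premolars",
      "maxillary canines",
      "second permanent molars"
    ),
    teeth = list(
      c("31", "41"),
      c("16", "26", "36", "46"),
      c("32", "42"),
      c("11", "21"),
      c("12", "22"),
      c("33", "43", "34", "44"),
      c("14", "24"),
      c("35", "45"),
      c("13", "23"),
      c("17", "27", "37", "47")
    ),
    da_low  = c(9, 9,   9.5, 10, 10.5, 12, 13, NA, 14, 15),
    da_high = c(9, 9.5, 9.5, 10, 11,   13, 14, NA, 15, 15),
    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  if (include_maxillary_laterals) {
    base$excluded[base$step == 5L] <- FALSE
  }
  long <- tidyr::unnest(base, "teeth") |>
    rename(tooth_fdi = "teeth")
  assessed <- long |>
    filter(!.data$excluded) |>
    arrange(.data$da_low, .data$step) |>
    mutate(group = match(.data$step, unique(.data$step)))
  excluded <- long |>
    filter(.data$excluded) |>
    mutate(group = NA_integer_)
  bind_rows(assessed, excluded) |>
    select("group", "step", "label", "tooth_fdi", "da_low", "da_high", "excluded") |>
    arrange(.data$group, .data$step)
}

# one row per assessed group (group, label, da_low, da_high)
ladder_groups <- function(ladder) {
  ladder |>
    filter(!.data$excluded) |>
    distinct(.data$group, .data$label, .data$da_low, .data$da_high) |>
    arrange(.data$group)
}

validate_apex_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("tooth_fdi", "apex_status")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("apex records need column(s): ", paste(missing, collapse = ", ")))
  }
  parse_fdi(records$tooth_fdi)  # validates codes
  ok <- records$apex_status %in% c("closed", "open", "unassessable") | is.na(records$apex_status)
  if (!all(ok)) {
    abort(paste0(
      "apex_status must be closed/open/unassessable, got: ",
      paste(unique(records$apex_status[!ok]), collapse = ", ")
    ))
  }
  if ("root_fraction" %in% names(records)) {
    rf <- records$root_fraction
    if (any(!is.na(rf) & (rf < 0 | rf > 1))) {
      abort("root_fraction must lie in [0, 1]")
    }
    closed_frac <- !is.na(rf) & rf < 1 & records$apex_status %in% "closed"
    if (any(closed_frac)) {
      abort(paste0(
        "closed apices imply a complete root: tooth ",
        paste(records$tooth_fdi[closed_frac], collapse = ", "),
        " is closed with root_fraction < 1"
      ))
    }
  }
  invisible(records)
}

#' Apex-closure status of each ladder group
#'
#' A group is `closed` when every assessable member tooth has a closed apex,
#' `open` when any assessable member is open, and `unknown` when no member is
#' assessable. Teeth absent from `records`, or recorded as `unassessable`,
#' do not count; the contralateral tooth of a pair therefore decides alone
#' when one side is unreadable.
#'
#' @param records data frame of per-tooth observations for one subject with
#'   columns `tooth_fdi`, `apex_status` (`closed`/`open`/`unassessable`) and
#'   optionally `root_fraction`.
#' @param ladder ladder table from [becker_ladder()].
#' @return A tibble with one row per assessed group: `group`, `label`,
#'   `da_low`, `da_high`, `status`, and the counts `n_closed`, `n_open`,
#'   `n_unassessable`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   tooth_fdi = c("31", "41", "36", "46"),
#'   apex_status = c("closed", "closed", "open", "open")
#' )
#' group_status(rec)
group_status <- function(records, ladder = becker_ladder()) {
  validate_apex_records(records)
  records <- records |>
    mutate(apex_status = ifelse(is.na(.data$apex_status), "unassessable", .data$apex_status))
  joined <- ladder |>
    filter(!.data$excluded) |>
    left_join(records[c("tooth_fdi", "apex_status")], by = "tooth_fdi") |>
    mutate(apex_status = ifelse(is.na(.data$apex_status), "unassessable", .data$apex_status))
  joined |>
    group_by(.data$group, .data$label, .data$da_low, .data$da_high) |>
    summarise(
      n_closed = sum(.data$apex_status == "closed"),
      n_open = sum(.data$apex_status == "open"),
      n_unassessable = sum(.data$apex_status == "unassessable"),
      .groups = "drop"
    ) |>
    mutate(status = case_when(
      .data$n_open > 0 ~ "open",
      .data$n_closed > 0 ~ "closed",
      TRUE ~ "unknown"
    )) |>
    arrange(.data$group) |>
    select("group", "label", "da_low", "da_high", "status",
           "n_closed", "n_open", "n_unassessable")
}

# The ladder walk on a vector of group statuses ("closed"/"open"/"unknown"),
# in group order. Returns the index k of the last closed group in the
# longest closed-or-unknown prefix (0 if none) plus audit flags. Kept free of
# data-frame machinery so it can be enumerated exhaustively.
becker_walk <- function(status) {
  n <- length(status)
  first_open <- which(status == "open")[1]
  scan_end <- if (is.na(first_open)) n else first_open - 1L
  closed_in_prefix <- which(status[seq_len(scan_end)] == "closed")
  k <- if (length(closed_in_prefix) == 0L) 0L else max(closed_in_prefix)
  flags <- character(0)
  if (any(status == "unknown")) flags <- c(flags, "incomplete_data")
  if (!is.na(first_open) && any(status[seq(first_open, n)] == "closed")) {
    flags <- c(flags, "inconsistent_sequence")
  }
  list(k = k, flags = flags)
}

collapse_range <- function(low, high, point = c("midpoint", "low", "high")) {
  point <- match.arg(point)
  switch(point, midpoint = (low + high) / 2, low = low, high = high)
}

#' Estimate dental age from root apexification (stepwise ladder)
#'
#' Walks the eruption-timing ladder and reads the dental age of the last
#' group whose apices are all closed. Groups with no assessable member are
#' skipped without breaking the walk (flag `incomplete_data`); a closed group
#' lying above an open one is reported with flag `inconsistent_sequence` and
#' the prefix answer is returned. When the first rung (mandibular central
#' incisors) is still open the subject is below the ladder's floor and the
#' estimate is delegated to [estimate_subnine()], which interpolates on root
#' fractions.
#'
#' @inheritParams group_status
#' @param anchors per-tooth root-development anchors for the sub-nine
#'   fallback, see [subnine_anchors()].
#' @param point how a ladder range such as 12–13 collapses to a point
#'   estimate: `"midpoint"` (default), `"low"` or `"high"`.
#' @return A one-row tibble: `method`, `da_point`, `da_low`, `da_high`,
#'   `group` (ladder rung used, `NA` on the sub-nine path), `flags`
#'   (comma-separated subset of `sub_nine`, `inconsistent_sequence`,
#'   `incomplete_data`, `low_confidence`).
#' @export
#' @examples
#' closed <- function(teeth) tibble::tibble(tooth_fdi = teeth, apex_status = "closed")
#' open <- function(teeth) tibble::tibble(tooth_fdi = teeth, apex_status = "open")
#' lad <- becker_ladder()
#' g1 <- lad$tooth_fdi[lad$group %in% 1]
#' rest <- lad$tooth_fdi[!lad$excluded & !lad$group %in% 1]
#' estimate_becker(rbind(closed(g1), open(rest)))
estimate_becker <- function(records,
                            ladder = becker_ladder(),
                            anchors = subnine_anchors(),
                            point = c("midpoint", "low", "high")) {
  point <- match.arg(point)
  validate_apex_records(records)
  assessed_teeth <- ladder$tooth_fdi[!ladder$excluded]
  assessable <- records$apex_status %in% c("closed", "open") &
    records$tooth_fdi %in% assessed_teeth
  if (!any(assessable)) {
    abort("empty assessment: no assessable apex record on any assessed tooth")
  }
  st <- group_status(records, ladder)
  walk <- becker_walk(st$status)

  if (walk$k == 0L) {
    # first rung not closed: below the ladder floor, interpolate root fractions
    est <- estimate_subnine(records, anchors = anchors)
    extra <- walk$flags[walk$flags == "inconsistent_sequence"]
    est$flags <- flags_chr(c(strsplit(est$flags, ",")[[1]], extra))
    return(est)
  }

  low <- st$da_low[walk$k]
  high <- st$da_high[walk$k]
  tibble(
    method = "becker",
    da_point = collapse_range(low, high, point),
    da_low = low,
    da_high = high,
    group = walk$k,
    flags = flags_chr(c(walk$flags, if (high < 9) "sub_nine"))
  )
}

#' Root-development anchors for the sub-nine fallback
#'
#' For each permanent tooth (third molars excluded) the age at which root
#' formation begins (`root_start_age`) and the age of apex closure
#' (`apex_age`). Defaults are synthetic: apex ages are anchored to the onset
#' (da_low) of each tooth's ladder rung (10.5 for the excluded maxillary
#' lateral incisors, 13.5 for the mandibular second premolars), and root
#' formation is
#' taken to span six years, which places functional eruption (apex minus
#' three years) at one half of final root length. Populations with different
#' eruption timing can supply their own table.
#'
#' @param root_duration years from root start to apex closure (default 6).
#' @return A tibble with `tooth_fdi`, `root_start_age`, `apex_age`.
#' @export
subnine_anchors <- function(root_duration = 6) {
  apex <- tooth_closure_ages()
  tibble(
    tooth_fdi = names(apex),
    root_start_age = unname(apex) - root_duration,
    apex_age = unname(apex)
  )
}

# Canonical per-tooth apex-closure ages (years): the onset (da_low) of each
# tooth's ladder rung; 10.5 / 13.5 for the two excluded groups. Shared by the
# sub-nine interpolation anchors and the simulator's maturation defaults.
tooth_closure_ages <- function() {
  c(
    `31` = 9, `41` = 9,
    `16` = 9, `26` = 9, `36` = 9, `46` = 9,
    `32` = 9.5, `42` = 9.5,
    `11` = 10, `21` = 10,
    `12` = 10.5, `22` = 10.5,
    `33` = 12, `43` = 12, `34` = 12, `44` = 12,
    `14` = 13, `24` = 13,
    `35` = 13.5, `45` = 13.5,
    `13` = 14, `23` = 14,
    `17` = 15, `27` = 15, `37` = 15, `47` = 15
  )
}

#' Estimate dental age below the ladder floor from root fractions
#'
#' Before the mandibular central incisors apexify (dental age under ~9) no
#' rung of the ladder is closed, so age is read from the proportion of final
#' root length each developing tooth has reached: for a tooth with fraction
#' `f`, interpolated age = `root_start_age + f * (apex_age - root_start_age)`,
#' and the estimate is the mean over contributing teeth. Such readings are
#' inherently softer than an apexification call, so `low_confidence` is
#' always flagged (plus `sub_nine` when the estimate falls below 9).
#'
#' @inheritParams estimate_becker
#' @return A one-row tibble in the same shape as [estimate_becker()].
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   tooth_fdi = c("31", "41", "36", "46"),
#'   apex_status = "open",
#'   root_fraction = c(2 / 3, 2 / 3, 0.5, 0.5)
#' )
#' estimate_subnine(rec)
estimate_subnine <- function(records, anchors = subnine_anchors()) {
  validate_apex_records(records)
  if (!"root_fraction" %in% names(records)) {
    abort("sub-nine estimate requires root fractions")
  }
  contrib <- records |>
    filter(.data$apex_status == "open", !is.na(.data$root_fraction)) |>
    inner_join(anchors, by = "tooth_fdi")
  if (nrow(contrib) == 0L) {
    abort("sub-nine estimate requires root fractions")
  }
  ages <- contrib$root_start_age +
    contrib$root_fraction * (contrib$apex_age - contrib$root_start_age)
  pt <- mean(ages)
  tibble(
    method = "becker",
    da_point = pt,
    da_low = pt,
    da_high = pt,
    group = NA_integer_,
    flags = flags_chr(c("low_confidence", if (pt < 9) "sub_nine"))
  )
}
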