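ladder <- becker_ladder()

test_that("the ladder has the documented structure", {
  groups <- ladder |> dplyr::filter(!excluded) |> dplyr::distinct(group, da_low, da_high)
  expect_equal(nrow(groups), 8L)
  expect_true(all(diff(groups$da_low[order(groups$group)]) >= 0))
  expect_true(all(groups$da_low <= groups$da_high))
  excluded <- ladder |> dplyr::filter(excluded)
  expect_setequal(excluded$tooth_fdi, c("12", "22", "35", "45"))
  # rung values: DA of each group in walk order
  ord <- groups[order(groups$group), ]
  expect_equal(ord$da_low, c(9, 9, 9.5, 10, 12, 13, 14, 15))
  expect_equal(ord$da_high, c(9, 9.5, 9.5, 10, 13, 14, 15, 15))
})

test_that("group status is closed only when every assessable member is closed", {
  # all four first molars closed -> closed
  st <- group_status(closed_records(c("16", "26", "36", "46")))
  expect_equal(st$status[st$group == 2], "closed")
  # bilateral fallback: one central incisor closed, the other missing
  st <- group_status(closed_records("31"))
  expect_equal(st$status[st$group == 1], "closed")
  # any open member blocks the group
  st <- group_status(dplyr::bind_rows(closed_records("33"), open_records("34")))
  expect_equal(st$status[st$group == 5], "open")
  # unassessable-only group is unknown, not an error
  st <- group_status(tibble::tibble(tooth_fdi = c("31", "41"), apex_status = "unassessable"))
  expect_equal(st$status[st$group == 1], "unknown")
})

test_that("the stepwise walk reproduces the printed rung readings", {
  run <- function(k) {
    estimate_becker(dplyr::bind_rows(
      closed_records(ladder_teeth_upto(k)),
      open_records(ladder_teeth_above(k))
    ))
  }
  expect_equal(run(1)$da_point, 9)
  expect_equal(run(3)$da_point, 9.5)   # molars + mandibular laterals last closed
  expect_equal(run(4)$da_point, 10)
  expect_equal(run(5)$da_low, 12)
  expect_equal(run(6)$da_low, 13)
  expect_equal(run(7)$da_low, 14)
  expect_equal(run(8)$da_point, 15)
  # midpoint collapse of a range
  expect_equal(run(2)$da_point, 9.25)
  expect_equal(run(2)$da_low, 9)
  expect_equal(run(2)$da_high, 9.5)
  # configurable collapse
  rec <- dplyr::bind_rows(closed_records(ladder_teeth_upto(5)), open_records(ladder_teeth_above(5)))
  expect_equal(estimate_becker(rec, point = "low")$da_point, 12)
  expect_equal(estimate_becker(rec, point = "high")$da_point, 13)
})

test_that("maxillary laterals are inert by default but usable behind the option", {
  base <- dplyr::bind_rows(closed_records(ladder_teeth_upto(4)), open_records(ladder_teeth_above(4)))
  with_laterals <- dplyr::bind_rows(base, closed_records(c("12", "22")))
  # default: toggling the excluded teeth changes nothing
  expect_equal(estimate_becker(base), estimate_becker(with_laterals))
  expect_equal(
    estimate_becker(dplyr::bind_rows(base, open_records(c("12", "22", "35", "45")))),
    estimate_becker(base)
  )
  # opted in: the lateral incisors become the last closed rung, DA 10.5-11
  lad_l <- becker_ladder(include_maxillary_laterals = TRUE)
  est <- estimate_becker(with_laterals, ladder = lad_l)
  expect_equal(est$da_low, 10.5)
  expect_equal(est$da_high, 11)
})

test_that("unknown groups are skipped; closed groups above an open one are flagged", {
  # G2 unknown but G1, G3 closed -> walk reaches 3
  status <- c("closed", "unknown", "closed", rep("open", 5))
  est <- estimate_becker(records_from_status(status))
  expect_equal(est$da_point, 9.5)
  expect_true(has_flag(est$flags, "incomplete_data"))
  # closed group above an open one: prefix answer plus flag
  status <- c("closed", "closed", "open", "unknown", "closed", rep("open", 3))
  est <- estimate_becker(records_from_status(status))
  expect_equal(est$da_point, 9.25)
  expect_equal(c(est$da_low, est$da_high), c(9, 9.5))
  expect_true(has_flag(est$flags, "inconsistent_sequence"))
})

test_that("degenerate assessments error informatively", {
  expect_error(
    estimate_becker(tibble::tibble(tooth_fdi = "31", apex_status = "unassessable")),
    "empty assessment"
  )
  expect_error(
    estimate_becker(tibble::tibble(tooth_fdi = character(), apex_status = character())),
    "empty assessment"
  )
  # below the floor without fractions
  expect_error(
    estimate_becker(open_records(c("31", "41"))),
    "root fractions"
  )
  # invalid records
  expect_error(
    estimate_becker(tibble::tibble(tooth_fdi = "31", apex_status = "shut")),
    "apex_status"
  )
  expect_error(
    estimate_becker(
      tibble::tibble(tooth_fdi = "31", apex_status = "closed", root_fraction = 0.5)
    ),
    "closed"
  )
})

test_that("sub-nine interpolation reads age from root fractions", {
  # two-thirds root on the central incisors, half on molars and laterals:
  # the reading should land near 6 years
  rec <- tibble::tibble(
    tooth_fdi = c("31", "41", "16", "26", "36", "46", "32", "42"),
    apex_status = "open",
    root_fraction = c(2 / 3, 2 / 3, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  )
  est <- estimate_subnine(rec)
  expect_lt(abs(est$da_point - 6), 0.75)
  expect_true(has_flag(est$flags, "sub_nine"))
  expect_true(has_flag(est$flags, "low_confidence"))
  # interpolation endpoints
  anchors <- subnine_anchors()
  full <- tibble::tibble(
    tooth_fdi = c("31", "36"), apex_status = "open", root_fraction = 1
  )
  expect_equal(
    estimate_subnine(full)$da_point,
    mean(anchors$apex_age[anchors$tooth_fdi %in% c("31", "36")])
  )
  zero <- tibble::tibble(tooth_fdi = "31", apex_status = "open", root_fraction = 0)
  expect_equal(
    estimate_subnine(zero)$da_point,
    anchors$root_start_age[anchors$tooth_fdi == "31"]
  )
  # estimate_becker delegates when the first rung is open
  delegated <- estimate_becker(rec)
  expect_equal(delegated$da_point, est$da_point)
})

test_that("walk agrees with the longest-closed-prefix oracle on all 3^8 vectors", {
  vectors <- all_status_vectors(8)
  impl <- lapply(vectors, dentage:::becker_walk)
  orac <- lapply(vectors, oracle_walk)
  expect_identical(
    vapply(impl, function(w) w$k, integer(1)),
    vapply(orac, function(o) o$k, integer(1))
  )
  expect_identical(
    vapply(impl, function(w) "incomplete_data" %in% w$flags, logical(1)),
    vapply(orac, function(o) o$incomplete, logical(1))
  )
  expect_identical(
    vapply(impl, function(w) "inconsistent_sequence" %in% w$flags, logical(1)),
    vapply(orac, function(o) o$inconsistent, logical(1))
  )
})

test_that("full estimator path matches the oracle on sampled status vectors", {
  set.seed(11)
  vectors <- all_status_vectors(8)
  groups <- ladder_groups_tbl()
  picks <- sample(length(vectors), 150)
  checked <- 0L
  for (i in picks) {
    status <- vectors[[i]]
    o <- oracle_walk(status)
    if (o$k == 0) next  # floor cases need fractions; covered elsewhere
    est <- estimate_becker(records_from_status(status))
    expect_equal(
      c(est$da_low, est$da_high),
      c(groups$da_low[o$k], groups$da_high[o$k])
    )
    checked <- checked + 1L
  }
  expect_gt(checked, 50)
})

test_that("closing any group never lowers the estimate (monotonicity)", {
  groups <- ladder_groups_tbl()
  point_of <- function(status) {
    k <- dentage:::becker_walk(status)$k
    if (k == 0) NA_real_ else (groups$da_low[k] + groups$da_high[k]) / 2
  }
  vectors <- all_status_vectors(8)
  violations <- 0L
  comparisons <- 0L
  for (status in vectors) {
    base_point <- point_of(status)
    if (is.na(base_point)) next
    for (g in which(status == "open")) {
      flipped <- status
      flipped[g] <- "closed"
      comparisons <- comparisons + 1L
      if (point_of(flipped) < base_point) violations <- violations + 1L
    }
  }
  expect_gt(comparisons, 5000)
  expect_equal(violations, 0L)
})
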