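# Direct Monte-Carlo implementation of the maturation model: closure ages,
# longest-closed-prefix read-off and root-fraction fallback written as plain
# formulas, independent of the package's simulator and estimator code paths.
oracle_mean_bias <- function(design, params, n_draws = 20000, seed = 99) {
  set.seed(seed)
  groups <- ladder_groups_tbl()
  lad <- becker_ladder()
  assessed <- lad[!lad$excluded, ]
  mu <- params$mu
  cells <- design[rep(seq_len(nrow(design)), design$n), c("age", "sex")]
  draws <- cells[sample(nrow(cells), n_draws, replace = TRUE), ]
  bias <- numeric(n_draws)
  group_of <- assessed$group[match(names(mu), assessed$tooth_fdi)]
  for (i in seq_len(n_draws)) {
    ca <- runif(1, draws$age[i], draws$age[i] + 1)
    delta <- rnorm(1, 0, params$subject_sd)
    shift <- params$population_shift + if (draws$sex[i] == "F") params$sex_advance else 0
    closure <- unname(mu) + delta + rnorm(length(mu), 0, params$tooth_sd) - shift
    closed <- ca >= closure
    # group closed iff all member teeth closed (excluded teeth carry NA group)
    k <- 0L
    for (g in seq_len(nrow(groups))) {
      if (!all(closed[which(group_of == g)])) break
      k <- g
    }
    if (k > 0) {
      est <- (groups$da_low[k] + groups$da_high[k]) / 2
    } else {
      frac <- pmin(1, pmax(0, (ca - (closure - params$root_duration)) / params$root_duration))
      open_teeth <- !closed
      anchors_apex <- unname(mu)   # anchors share the canonical closure ages
      est <- mean((anchors_apex[open_teeth] - params$root_duration) +
                    frac[open_teeth] * params$root_duration)
    }
    bias[i] <- est - ca
  }
  mean(bias)
}

test_that("the default design reproduces the study's age-sex margins", {
  design <- age_sex_design()
  expect_equal(sum(design$n), 377L)
  expect_equal(sum(design$n[design$sex == "M"]), 193L)
  expect_equal(sum(design$n[design$sex == "F"]), 184L)
  expect_equal(design$n[design$sex == "F" & design$age == 8], 14L)
  expect_equal(design$n[design$sex == "M" & design$age == 8], 17L)
  expect_error(age_sex_design(8:9, male = 1, female = c(1, 1)), "length")
})

test_that("simulation is deterministic given the master seed", {
  d <- age_sex_design(c(9, 13), c(3, 3), c(3, 3))
  a <- simulate_cohort(d, seed = 123)
  b <- simulate_cohort(d, seed = 123)
  expect_identical(a, b)
  c2 <- simulate_cohort(d, seed = 124)
  expect_false(identical(a, c2))
  # ratings too
  ra <- simulate_ratings(a, seed = 55)
  rb <- simulate_ratings(b, seed = 55)
  expect_identical(ra, rb)
})

test_that("adding later subjects never perturbs earlier ones", {
  small <- age_sex_design(c(9, 13), c(2, 0), c(2, 0))
  bigger <- age_sex_design(c(9, 13), c(2, 4), c(2, 0))
  a <- simulate_cohort(small, seed = 77)
  b <- simulate_cohort(bigger, seed = 77)
  shared <- intersect(unique(a$subject_id), unique(b$subject_id))
  expect_equal(
    a[a$subject_id %in% shared, ],
    b[b$subject_id %in% shared, ]
  )
})

test_that("a zero-noise subject is fully determined by the closure ladder", {
  params <- maturation_params(subject_sd = 0, tooth_sd = 0, sex_advance = 0)
  coh <- simulate_cohort(age_sex_design(14, male = 1, female = 0), params, seed = 6)
  ca <- coh$ca_years[1]
  mu <- dentage:::tooth_closure_ages()
  expect_equal(
    coh$apex_status == "closed",
    unname(ca >= mu[coh$tooth_fdi])
  )
  # every rung through the maxillary canines is closed, second molars open
  est <- estimate_becker(coh)
  expect_equal(est$da_point, 14.5)
})

test_that("closed teeth form an age-consistent set when per-tooth noise is off", {
  params <- maturation_params(tooth_sd = 0)
  coh <- simulate_cohort(age_sex_design(c(9, 11, 13), c(4, 4, 4), c(4, 4, 4)),
                         params, seed = 31)
  coherent <- coh |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(
      ok = max(c(-Inf, true_closure_age[apex_status == "closed"])) <=
        min(c(Inf, true_closure_age[apex_status == "open"]))
    )
  expect_true(all(coherent$ok))
})

test_that("root fractions are linear progress clipped to [0, 1]", {
  coh <- simulate_cohort(age_sex_design(c(8, 12), c(5, 5), c(5, 5)), seed = 17)
  open_rows <- coh[coh$apex_status == "open", ]
  expect_true(all(open_rows$root_fraction >= 0 & open_rows$root_fraction <= 1))
  expected <- pmin(1, pmax(0, (open_rows$ca_years - (open_rows$true_closure_age - 6)) / 6))
  expect_equal(open_rows$root_fraction, expected)
  expect_true(all(is.na(coh$root_fraction[coh$apex_status == "closed"])))
})

test_that("simulated mean ladder bias matches the direct model computation", {
  # The ladder's rung spacing makes the read-off biased low on a cohort
  # spanning 8-16 (the 10 -> 12-13 gap alone contributes about -1.5 y over
  # ages 11-12.4); the simulator and a from-scratch Monte-Carlo of the same
  # model must agree on that number.
  params <- maturation_params()
  coh <- simulate_cohort(age_sex_design(), params, seed = 42)
  est <- estimate_cohort(coh, method = "becker")
  sim_bias <- mean(est$da_point - est$ca_years)
  oracle_bias <- oracle_mean_bias(age_sex_design(), params)
  expect_lt(abs(sim_bias - oracle_bias), 0.1)
  expect_lt(sim_bias, 0)  # the rung-gap effect is real and negative
})

test_that("noise-free ratings are identical across raters and sessions", {
  coh <- simulate_cohort(age_sex_design(c(9, 12), c(4, 4), c(4, 4)),
                         maturation_params(rater_error = 0), seed = 12)
  rated <- simulate_ratings(coh, raters = 2, sessions = 2,
                            params = maturation_params(rater_error = 0), seed = 12)
  est <- estimate_cohort(rated, method = "becker")
  wide <- est |>
    dplyr::mutate(col = paste(rater_id, session_id)) |>
    dplyr::select(subject_id, col, da_point) |>
    tidyr::pivot_wider(names_from = col, values_from = da_point)
  spread <- apply(as.matrix(wide[, -1]), 1, function(r) diff(range(r)))
  expect_true(all(spread == 0))
  res <- icc(est |> dplyr::filter(session_id == "S1"))
  expect_equal(res$estimate[res$form == "ICC3" & res$unit == "single"], 1)
})

test_that("reliability degrades monotonically with rater error", {
  d <- age_sex_design(c(9, 11, 13), c(9, 8, 8), c(9, 8, 8))
  coh <- simulate_cohort(d, seed = 20)
  icc_at <- function(p_err) {
    params <- maturation_params(rater_error = p_err, boundary_window = 1.5)
    rated <- simulate_ratings(coh, raters = 2, sessions = 1, params = params, seed = 20)
    est <- estimate_cohort(rated, method = "becker")
    res <- icc(est)
    res$estimate[res$form == "ICC3" & res$unit == "single"]
  }
  series <- vapply(c(0, 0.1, 0.2, 0.3), icc_at, numeric(1))
  expect_equal(series[1], 1)
  expect_true(all(diff(series) <= 0.02))  # non-increasing up to simulation noise
  expect_lt(series[4], 0.95)              # heavy noise is clearly visible
})

test_that("rater-specific bias separates intra- from inter-rater reliability", {
  d <- age_sex_design(c(9, 11, 13, 14), c(7, 6, 6, 6), c(7, 6, 6, 6))
  coh <- simulate_cohort(d, seed = 26)
  params <- maturation_params(rater_error = 0.05, rater_bias_sd = 0.75)
  rated <- simulate_ratings(coh, raters = 2, sessions = 2, params = params, seed = 26)
  est <- estimate_cohort(rated, method = "becker")
  panel <- icc_panel(est)
  intra <- mean(panel$icc[panel$comparison == "intra"])
  inter <- mean(panel$icc[panel$comparison == "inter"])
  expect_gt(intra, inter)
})
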