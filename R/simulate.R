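#' Age-by-sex cohort design
#'
#' Counts of subjects per (integer age, sex) cell. The default reproduces the
#' reference study sample: ages 8–15, 193 males and 184 females, 377 in
#' total.
#'
#' @param ages integer ages (lower cell edges).
#' @param male,female subject counts per age, same length as `ages`.
#' @return A long tibble: `age`, `sex` (`F`/`M`), `n`.
#' @export
#' @examples
#' age_sex_design()            # the default 377-subject design
#' age_sex_design(10:11, male = c(5, 5), female = c(5, 5))
age_sex_design <- function(ages = 8:15,
                           male = c(17, 22, 18, 32, 29, 38, 22, 15),
                           female = c(14, 15, 26, 23, 33, 40, 21, 12)) {
  if (length(male) != length(ages) || length(female) != length(ages)) {
    abort("male and female counts must match the length of ages")
  }
  if (any(male < 0) || any(female < 0)) abort("design counts must be >= 0")
  bind_rows(
    tibble(age = ages, sex = "M", n = as.integer(male)),
    tibble(age = ages, sex = "F", n = as.integer(female))
  ) |>
    filter(.data$n > 0) |>
    arrange(.data$age, .data$sex)
}

#' Maturation model parameters for the cohort simulator
#'
#' The generator draws, for subject i and tooth t, an apex-closure age
#' `mu_t + delta_i + eps_it - shift` where `mu_t` is the per-tooth mean
#' closure age, `delta_i ~ N(0, subject_sd)` is a shared maturation tempo,
#' `eps_it ~ N(0, tooth_sd)` is per-tooth noise, and `shift` is
#' `population_shift` plus `sex_advance` for girls (positive = earlier
#' maturation). Root formation spans `root_duration` years ending at
#' closure; staging thresholds sit at fixed offsets below the closure age
#' (stage H is entered at apex closure). Rater noise: a reading whose
#' chronological age lies within `boundary_window` of the (rater-shifted)
#' closure age flips with probability `rater_error`; `rater_bias_sd` gives
#' each rater a systematic threshold offset.
#'
#' @param mu named numeric vector of per-tooth mean closure ages (defaults
#'   to the ladder DA onsets, marked synthetic).
#' @param subject_sd SD (years) of the shared subject tempo (default 0.5).
#' @param tooth_sd SD (years) of per-tooth noise (default 0.25).
#' @param population_shift systematic advancement in years (default 0).
#' @param sex_advance additional advancement for females (default 0.25).
#' @param root_duration years from root start to apex closure (default 6).
#' @param stage_offsets named offsets (years before closure) at which stages
#'   A–H are entered; must be strictly increasing and end at 0.
#' @param rater_error misreading probability near a closure boundary
#'   (default 0.05, must be in \[0, 0.5\]).
#' @param boundary_window half-width (years) of the uncertain zone around a
#'   closure age (default 0.5).
#' @param rater_bias_sd SD of per-rater systematic threshold offsets
#'   (default 0).
#' @return A `maturation_params` list.
#' @export
maturation_params <- function(mu = tooth_closure_ages(),
                              subject_sd = 0.5,
                              tooth_sd = 0.25,
                              population_shift = 0,
                              sex_advance = 0.25,
                              root_duration = 6,
                              stage_offsets = c(
                                A = -7, B = -6, C = -5, D = -4,
                                E = -3, F = -2, G = -1, H = 0
                              ),
                              rater_error = 0.05,
                              boundary_window = 0.5,
                              rater_bias_sd = 0) {
  if (subject_sd < 0 || tooth_sd < 0) abort("subject_sd and tooth_sd must be >= 0")
  if (rater_error < 0 || rater_error > 0.5) abort("rater_error must lie in [0, 0.5]")
  if (any(diff(stage_offsets) <= 0)) abort("stage_offsets must be strictly increasing")
  if (!identical(names(stage_offsets), c("A", "B", "C", "D", "E", "F", "G", "H"))) {
    abort("stage_offsets must be named A through H")
  }
  structure(
    list(
      mu = mu, subject_sd = subject_sd, tooth_sd = tooth_sd,
      population_shift = population_shift, sex_advance = sex_advance,
      root_duration = root_duration, stage_offsets = stage_offsets,
      rater_error = rater_error, boundary_window = boundary_window,
      rater_bias_sd = rater_bias_sd
    ),
    class = "maturation_params"
  )
}

# Deterministic stream splitting: one master seed, one substream per index
# tuple, so adding a subject (or rater/session) never perturbs earlier draws.
split_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (idx in c(...)) {
    h <- (h * 69069 + as.double(idx) * 10007 + 1) %% 2147483647
  }
  as.integer(h)
}

#' Simulate a dental-maturation cohort
#'
#' Draws one subject per design slot: chronological age uniform within the
#' age cell, a shared maturation tempo, per-tooth closure ages, apex status
#' (closed iff CA has passed the closure age), root fractions for open teeth
#' (linear progress over the root-formation span, clipped to \[0, 1\]), and
#' staging for the seven left mandibular teeth. Deterministic given `seed`;
#' truth columns `true_closure_age` and `true_offset` are retained for the
#' rater-noise generator and for diagnostics.
#'
#' @param design age-by-sex design from [age_sex_design()].
#' @param params a [maturation_params()] object.
#' @param seed integer master seed (required).
#' @return A long cohort tibble in the [read_cohort()] schema plus the two
#'   truth columns, rated as `rater_id = "R1"`, `session_id = "S1"`.
#' @export
#' @examples
#' cohort <- simulate_cohort(age_sex_design(10:11, c(2, 2), c(2, 2)), seed = 7)
#' dplyr::count(cohort, subject_id)
simulate_cohort <- function(design = age_sex_design(),
                            params = maturation_params(),
                            seed) {
  stopifnot(inherits(params, "maturation_params"))
  if (missing(seed)) abort("simulate_cohort requires an explicit seed")
  if (nrow(design) == 0L || sum(design$n) == 0L) abort("empty design")
  teeth <- names(params$mu)
  stage_teeth <- paste0("3", 1:7)
  slots <- design |> tidyr::uncount(.data$n)
  subjects <- purrr::pmap(
    list(slots$age, slots$sex, seq_len(nrow(slots))),
    function(age, sex, i) {
      old <- .Random.seed_store()
      on.exit(.Random.seed_restore(old))
      set.seed(split_seed(seed, 1L, i))
      ca <- runif(1, age, age + 1)
      delta <- rnorm(1, 0, params$subject_sd)
      eps <- rnorm(length(teeth), 0, params$tooth_sd)
      shift <- params$population_shift + if (sex == "F") params$sex_advance else 0
      closure <- unname(params$mu) + delta + eps - shift
      root_start <- closure - params$root_duration
      closed <- ca >= closure
      frac <- pmin(1, pmax(0, (ca - root_start) / params$root_duration))
      stage <- rep(NA_character_, length(teeth))
      idx <- match(stage_teeth, teeth)
      for (j in idx) {
        entered <- closure[j] + params$stage_offsets
        passed <- sum(ca >= entered)
        stage[j] <- if (passed == 0L) "UNFORMED" else names(params$stage_offsets)[passed]
      }
      tibble(
        subject_id = sprintf("S%04d", i),
        sex = sex,
        ca_years = ca,
        rater_id = "R1",
        session_id = "S1",
        tooth_fdi = teeth,
        apex_status = ifelse(closed, "closed", "open"),
        root_fraction = ifelse(closed, NA_real_, frac),
        demirjian_stage = stage,
        true_closure_age = closure,
        true_offset = delta
      )
    }
  )
  list_rbind(subjects)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Replicate a cohort under independent rater/session noise
#'
#' Emulates a reliability design: each rater re-reads every subject in each
#' session. A rater carries a systematic threshold offset (SD
#' `rater_bias_sd`); a tooth whose chronological age lies within
#' `boundary_window` of the rater-shifted closure age flips apex status with
#' probability `rater_error`, and a recorded stage is misread one stage up
#' or down with the same probability. Outside the uncertain zone apex
#' readings are faithful. Deterministic given `seed`.
#'
#' @param cohort cohort from [simulate_cohort()] (the truth columns are
#'   required).
#' @param raters,sessions counts (default 2 each).
#' @param params a [maturation_params()] object.
#' @param seed integer master seed (required).
#' @return The cohort replicated per (rater, session) with `rater_id`
#'   `"R1"`, `"R2"`, ... and `session_id` `"S1"`, `"S2"`, ...
#' @export
simulate_ratings <- function(cohort, raters = 2, sessions = 2,
                             params = maturation_params(), seed) {
  stopifnot(inherits(params, "maturation_params"))
  if (missing(seed)) abort("simulate_ratings requires an explicit seed")
  if (!all(c("true_closure_age", "true_offset") %in% names(cohort))) {
    abort("simulate_ratings needs the truth columns simulate_cohort produces")
  }
  subj_ids <- unique(cohort$subject_id)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))

  rater_bias <- vapply(seq_len(raters), function(r) {
    set.seed(split_seed(seed, 2L, r))
    rnorm(1, 0, params$rater_bias_sd)
  }, numeric(1))

  stage_pool <- STAGE_LEVELS
  out <- list()
  for (r in seq_len(raters)) {
    for (s in seq_len(sessions)) {
      read <- purrr::map(seq_along(subj_ids), function(i) {
        rows <- cohort[cohort$subject_id == subj_ids[i], ]
        set.seed(split_seed(seed, 3L, i, r, s))
        shifted <- rows$true_closure_age + rater_bias[r]
        near <- abs(rows$ca_years - shifted) < params$boundary_window
        base_closed <- rows$ca_years >= shifted
        flip <- near & runif(nrow(rows)) < params$rater_error
        closed <- xor(base_closed, flip)
        stage <- rows$demirjian_stage
        has_stage <- !is.na(stage)
        stage_flip <- has_stage & runif(nrow(rows)) < params$rater_error
        if (any(stage_flip)) {
          pos <- match(stage[stage_flip], stage_pool)
          move <- sign(runif(sum(stage_flip)) - 0.5)
          move[move == 0] <- 1
          pos <- pmin(length(stage_pool), pmax(1, pos + move))
          stage[stage_flip] <- stage_pool[pos]
        }
        rows |>
          mutate(
            rater_id = paste0("R", r),
            session_id = paste0("S", s),
            apex_status = ifelse(closed, "closed", "open"),
            root_fraction = ifelse(closed, NA_real_, .data$root_fraction),
            root_fraction = ifelse(!closed & is.na(.data$root_fraction),
                                   pmin(1, pmax(0, (.data$ca_years - (shifted - params$root_duration)) /
                                                  params$root_duration)),
                                   .data$root_fraction),
            demirjian_stage = stage
          )
      })
      out <- c(out, read)
    }
  }
  list_rbind(out)
}
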