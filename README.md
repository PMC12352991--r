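# dentage

Dental age (DA) estimation for children and adolescents from panoramic
radiograph readings, and the statistics used to compare DA methods against
chronological age (CA) on a cohort.

Timing decisions in pediatric dentistry and orthodontics — extractions,
space maintenance, appliance choice — depend on a child's developmental
rather than calendar age. `dentage` implements two radiographic DA readings
and a complete method-comparison pipeline:

* **Stepwise apexification ladder.** Tooth groups are ordered by eruption
  timing, each carrying the DA at which its root apices close; the reading
  is the DA of the last group whose assessable members all show closed
  apices (root-apex closure is the most reliably identifiable landmark on a
  panoramic radiograph, occurring ~3 years after eruption). Formally, with
  rung values DA(1) ≤ … ≤ DA(8) and per-group closure indicators C(g),
  the estimate is DA(k) for k = max{g : C(1), …, C(g)} (unassessable
  groups skipped), with an interpolation fallback on root fractions below
  the first rung (DA < 9): age(t) = root_start(t) + f(t)·(apex(t) −
  root_start(t)), averaged over developing teeth.
* **Maturity-score staging.** The seven left mandibular teeth (FDI 31–37)
  are staged A–H, scored with sex-specific weights, summed to a maturity
  score S ≤ 100 and converted to DA on a sex-specific curve — implemented
  as a validated table engine (the published numeric tables are external
  reference material; a clearly synthetic table ships for testing, real
  tables load from CSV).
* **Agreement statistics.** Age-by-sex bias tables (mean DA − CA with
  sample SDs and per-stratum p-values), Wilcoxon signed-rank tests (exact
  tie-aware enumeration for n ≤ 25, tie- and continuity-corrected normal
  approximation above), Pearson correlation, OLS regression with a
  slope-equality interaction test, and the six-form Shrout–Fleiss
  intraclass correlation panel with F-based confidence intervals.
* **Cohort simulator.** Correlated per-tooth maturation (shared subject
  tempo + per-tooth noise), sex-specific and population-level advancement,
  root-fraction and staging generation, and two-rater/two-session
  misclassification noise, under a strict one-master-seed stream-splitting
  contract — so the whole pipeline is testable without radiographs.

## Worked example

```r
library(dentage)

# a subject whose molars and mandibular incisors are apexified,
# everything later still open:
lad <- becker_ladder()
records <- dplyr::bind_rows(
  tibble::tibble(tooth_fdi = lad$tooth_fdi[!is.na(lad$group) & lad$group <= 3],
                 apex_status = "closed"),
  tibble::tibble(tooth_fdi = lad$tooth_fdi[!lad$excluded & lad$group > 3],
                 apex_status = "open")
)
estimate_becker(records)
#> # A tibble: 1 × 6
#>   method da_point da_low da_high group flags
#>   <chr>     <dbl>  <dbl>   <dbl> <int> <chr>
#> 1 becker      9.5    9.5     9.5     3 ""
```

The reading is 9.5 years: the first permanent molars and mandibular lateral
incisors are the last closed rung. On a whole cohort:

```r
cohort <- read_cohort(system.file("extdata", "example_cohort.csv", package = "dentage"))
estimate_cohort(cohort)
#> # A tibble: 12 × 10
#>    subject_id sex   ca_years rater_id session_id method  da_point da_low da_high
#>    <chr>      <chr>    <dbl> <chr>    <chr>      <chr>      <dbl>  <dbl>   <dbl>
#>  1 S0001      F         8.31 R1       S1         becker      9      9       9
#>  2 S0001      F         8.31 R1       S1         demirj…    10.4   10.4    10.4
#>  3 S0002      M         8.56 R1       S1         becker      8.34   8.34    8.34
#>  4 S0002      M         8.56 R1       S1         demirj…     9.76   9.76    9.76
#>  5 S0003      F        10.4  R1       S1         becker     10     10      10
#>  ...
```

Each row is one (subject, method) estimate: point, range, and audit flags
(`sub_nine`, `incomplete_data`, `inconsistent_sequence`, `low_confidence`).
Subject S0002 is below the ladder floor, so the estimate (8.34) comes from
root-fraction interpolation. Downstream, `bias_table()` reproduces the
age-by-sex comparison layout, `compare_methods()` the correlation/slope
summary, and `icc()` / `icc_panel()` the reliability panel:

```r
coh   <- simulate_cohort(seed = 1)                       # 377-subject default design
rated <- simulate_ratings(coh, raters = 2, sessions = 2, seed = 1)
icc(estimate_cohort(dplyr::filter(rated, session_id == "S1"), method = "becker"))
#> Intraclass correlation (377 subjects x 2 raters/sessions; default display: ICC3 single)
#>  form    unit estimate lower upper
#>  ICC1  single    0.990 0.988 0.992
#>  ICC1 average    0.995 0.994 0.996
#>  ICC2  single    0.990 0.988 0.992
#>  ICC2 average    0.995 0.994 0.996
#>  ICC3  single    0.990 0.988 0.992
#>  ICC3 average    0.995 0.994 0.996
```

A thin command-line wrapper (`inst/cli/dentage.R`) exposes the same
pipeline as `simulate`, `estimate` and `compare` subcommands for shell use.

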