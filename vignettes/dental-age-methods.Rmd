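---
title: "Dental age estimation: the stepwise apexification ladder, maturity-score staging, and their agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dental age estimation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message = FALSE}
library(dentage)
library(dplyr)
```

## The problem

Pediatric dentists and orthodontists time interventions — extractions, space
maintenance, appliance choice — against a child's *dental* age (DA), the
developmental age implied by tooth formation, rather than the calendar
(chronological) age, CA. Tooth eruption is easily disturbed by local factors
(crowding, early loss of primary teeth, impaction), so accurate DA methods
read tooth *calcification* from radiographs instead. `dentage` implements
two such readings and the full statistical toolkit needed to compare them on
a cohort: an apexification ladder read directly off a panoramic radiograph,
and a table-driven maturity-score method, plus bias tables, signed-rank
tests, regression slope comparison, intraclass correlation, and a cohort
simulator that stands in for radiograph data.

## The apexification ladder

Root apex closure — the radiographic disappearance of the apical papilla —
is a sharply identifiable landmark that occurs roughly three years after a
tooth erupts. The ladder method groups the permanent teeth by eruption
timing and assigns each group the DA at which its apices close:

```{r}
becker_ladder() |> distinct(group, label, da_low, da_high, excluded)
```

The reading rule is: walk the rungs in order and report the DA of the *last*
group whose assessable members all show closed apices. Two groups with
notoriously variable development — maxillary lateral incisors and mandibular
second premolars — are excluded from the walk by default; the laterals can
be opted back in (`include_maxillary_laterals = TRUE`), in which case a
subject whose laterals are the last closed set reads DA 10.5–11.

Three situations the rule itself does not settle are handled as follows, and
each leaves an audit flag on the estimate:

* **Unassessable teeth.** A tooth absent from the records simply does not
  vote; within a left/right pair the contralateral tooth decides alone
  (development is strongly symmetric). A rung with no assessable member is
  skipped without breaking the walk (`incomplete_data`). Refusing to
  estimate whenever a single tooth is unreadable would make the method
  clinically useless; the flag preserves auditability.
* **Inconsistent sequences.** Per-tooth variability can close a later rung
  while an earlier one is still open. The walk stops at the first open rung
  and returns that prefix answer, flagged `inconsistent_sequence`, rather
  than erroring: the prefix is the defensible part of the evidence.
* **Range collapse.** Several rungs carry a range (12–13) but cohort
  statistics need a point per subject. The arithmetic midpoint is the
  default; `point = "low"`/`"high"` are available because no published
  collapse rule exists. This choice matters for bias statistics (see the
  calibration section below).

### Below the ladder floor

Before the mandibular central incisors apexify (DA < 9) no rung is closed.
The estimator then interpolates on the *proportion of final root length*
each developing tooth shows: a tooth whose root is a fraction `f` complete
is read at `root_start_age + f * (apex_age − root_start_age)`, and the
estimate is the mean over contributing teeth. The packaged anchor table
(`subnine_anchors()`) is synthetic but principled: apex ages sit at the
onset of each tooth's rung DA, and root formation is taken to span six
years, which puts functional eruption (apex − 3 y) at one half of final
root length — consistent with teeth erupting at one-half to two-thirds
root. Populations with different eruption timing can supply their own
table. These readings are softer than an apexification call, so they always
carry `low_confidence` (plus `sub_nine` below 9):

```{r}
estimate_subnine(tibble::tibble(
  tooth_fdi = c("31", "41", "16", "26", "36", "46", "32", "42"),
  apex_status = "open",
  root_fraction = c(2/3, 2/3, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
))
```

The flag rule is worth one note: the sub-nine path always lowers confidence,
but `sub_nine` itself is set only when the estimate actually falls below 9 —
with root fractions near 1 the interpolation legitimately reaches 9 or
above, and flagging such an estimate "sub-nine" would be self-contradictory.

## The maturity-score method

The seven left mandibular permanent teeth (FDI 31–37) are staged `A`–`H`
(plus `UNFORMED`), each stage carries a sex-specific self-weighted score,
the seven scores are summed to a maturity score (≤ 100), and the score is
converted to DA on a sex-specific curve. This package implements the method
as a *validated table engine*: the published numeric tables are reference
material that is licensed separately, so `dentage` ships a clearly synthetic
table (`demirjian_table()`) with the correct structure — scores
non-decreasing across stages within each tooth and sex, all-`H` total of
100, strictly increasing conversion knots — and real population tables are
supplied as CSV through `load_maturity_table()`, which enforces the same
invariants at load time. Conversion between knots is piecewise-linear, the
standard practical reading of published percentile curves; whether a study
interpolated or rounded its lookups is rarely stated, and interpolation is
the only choice that keeps the estimator monotone and continuous. Scores
outside the curve's support are clamped to the nearest endpoint and flagged
`low_confidence`. A subject missing any of the seven stages is a hard error
for this method (the usual inclusion criteria exclude such subjects; no
substitution is attempted).

## Agreement statistics

`bias_table()` stratifies per-subject estimates by sex and integer age
group and reports n, means and sample SDs (n − 1), the signed biases
DA − CA, the between-method difference, and per-stratum two-sided
signed-rank p-values, with per-sex and overall totals. Age groups are
`floor(CA)`: a child is "12" from the 12th birthday to the day before the
13th, which is how ages are stated clinically. Difference columns are
computed from per-subject differences at full precision, never from rounded
means. P-values print as three decimals floored at `<0.001`. No multiple-
testing correction is applied; per-stratum p-values are reported raw, as
agreement studies conventionally do.

The **signed-rank test** (`wilcoxon_signed_rank()`) uses midranks for tied
absolute differences. For n ≤ 25 the two-sided p-value comes from the exact
null distribution, computed by a generating-function convolution that
handles ties (doubling midranks to make them integral); above 25 a normal
approximation with tie correction and continuity correction takes over — the
convention of common reference implementations. Zero differences are dropped
before ranking (the test's original policy); the Pratt variant is available
via `zero_policy = "pratt"`. All-zero differences return p = 1 with a
degeneracy warning rather than an error.

**Correlation and regression** go through `stats::cor.test` and `stats::lm`
(`pearson_r()`, `linreg()`), and `slope_equality_test()` tests equality of
two methods' slopes on the same predictor via the interaction term of a
stacked model — a pure offset between methods deliberately does not
register.

**Reliability** uses the classical six-form intraclass correlation panel
computed from two-way ANOVA mean squares (`icc()`): one-way random, two-way
random absolute-agreement, and two-way mixed consistency, each for single
and averaged ratings, with F-based confidence intervals (Satterthwaite
degrees of freedom for the absolute-agreement form). Because ratings in a
reliability sub-study come from fixed, named examiners, ICC3 single is the
default display, but all six estimates are always returned — reliability
papers rarely say which form they used, and the honest output is the panel.
`icc_panel()` arranges a two-rater × two-session design into the usual
intra-rater (across sessions) and inter-rater (across raters) rows.

## The cohort simulator

Real radiograph cohorts are rarely shareable, so every pipeline stage is
exercised against `simulate_cohort()`. The maturation model is the minimal
structure that makes both bias and reliability simulations meaningful:

* tooth `t` of subject `i` closes at `mu_t + delta_i + eps_it − shift`,
  where `mu_t` is the per-tooth mean closure age, `delta_i ~ N(0,
  subject_sd)` is a shared maturation tempo (the component that creates
  between-method correlation within a subject), `eps_it ~ N(0, tooth_sd)`
  is per-tooth noise, and `shift` combines a population-level advancement
  with a sex advancement (girls mature earlier; default 0.25 y);
* apex status is `closed` exactly when CA has passed the closure age; open
  teeth carry the linear root-formation progress clipped to [0, 1];
* stages for teeth 31–37 are entered at fixed offsets below the closure age
  (stage H at closure, one stage per year by default);
* the default design reproduces the reference study's margins: ages 8–15,
  193 boys and 184 girls, 377 subjects, with CA uniform within each
  one-year cell (only integer-age cell counts are ever published);
* default `mu_t` is the onset (`da_low`) of the tooth's rung — the reading
  at the moment a rung closes then equals the rung's printed onset — and
  the same canonical table drives the sub-nine anchors, so the two halves
  of the estimator see one coherent population;
* rater noise: a reading within `boundary_window` (default 0.5 y) of the
  rater-shifted closure age flips with probability `rater_error`
  (default 0.05), stages are misread one step with the same probability,
  and `rater_bias_sd` gives each rater a systematic offset — which is what
  separates intra- from inter-rater reliability.

Randomness follows a strict stream-splitting contract: one master seed, one
derived substream per subject (and per subject × rater × session for
ratings), so adding a subject never perturbs earlier subjects and the same
seed always reproduces the same cohort bit for bit.

What the generator does *not* emulate: real stage-assignment ambiguity
(stages are generated from thresholds, not images), demographic structure
beyond the age × sex margins, missing or unassessable teeth (statuses are
always readable unless the user degrades them), secular trends, and any
correlation between apex reading errors and staging errors. Passing tests
therefore demonstrate that the *pipeline* is correct and that the methods'
statistical machinery behaves as designed — not that either method is
accurate on any real population.

## Calibration of the ladder read-off, and what "bias" means here

One genuinely instructive property of the ladder surfaced while validating
the simulator, and it is worth stating because it is a property of the
method, not of any implementation. Even when the population's closure ages
sit *exactly* on the ladder's printed DA values, the read-off is biased low
on a cohort spanning 8–16: the reading is a floor function onto the rung
values, and the rungs are not equally spaced. Between the maxillary central
incisors (DA 10) and the mandibular canines/first premolars (DA 12–13)
there is no rung at all, so every subject in that window reads DA 10 — a
bias approaching −1.5 y just before the next rung closes — while densely
rugged regions (9–10) contribute almost nothing. Integrating the staircase
against the default design's age distribution gives an expected mean bias
of about −0.3 y. The package's test suite checks exactly this: the
simulated pipeline's mean bias must agree (±0.1 y) with an independent
Monte-Carlo integration of the same staircase model written as plain
formulas. A systematic *population* advancement, by contrast, shifts the
whole staircase and survives the floor effect: injecting a +1.0 y
advancement moves the mean bias by +1.0 (±0.25) on the default design, and
the suite asserts that recovery. This is the mechanism by which a genuinely
advanced population shows up as positive observed bias even though the
pure read-off is floor-biased.

## Numerical choices and degenerate inputs

* Exact signed-rank enumeration switches to the normal approximation above
  n = 25; the suite checks the two agree to within 0.02 across n = 12–25.
* Ladder walks on fully unassessable dentitions error (`empty assessment`);
  sub-nine estimates without any root fraction error rather than guess.
* Single-subject strata report undefined (NA) SDs; empty strata are emitted
  with n = 0 so table layouts stay rectangular.
* ICC requires a complete matrix (no imputation), at least 2 raters and 5
  subjects.
* Cohort files are comma-separated UTF-8 with `.` decimals; parsing is
  locale-independent. Long (one row per tooth) format means partial
  dentitions need no sentinel values; unmentioned teeth are *unassessable*,
  never assumed open.
* CA from dates uses days/365.25; a plausibility window (default 3–25 y)
  warns without rejecting.

## Problem sizes used by the test suite

The suite enumerates all 3^8 = 6561 ladder status vectors against a
brute-force oracle, compares exact signed-rank p-values with full 2^n sign
enumeration up to n = 15, sizes the test at 2000 null replicates of n = 30,
checks ICC recovery of planted variance shares at 500 subjects, and runs
the full 377-subject design twice for the advancement-recovery check. These
sizes give comfortable Monte-Carlo margins for every asserted tolerance
while keeping a complete run to a few minutes on one CPU.

## Limitations

* The packaged maturity table is synthetic; substantive staging work
  requires the user's population tables.
* The ladder's anchor and closure-age defaults are illustrative for a
  generic modern population, not fitted to any dataset; the package
  forward-simulates and estimates but never *fits* maturation parameters.
* Both estimators consume human- or simulator-produced readings; no image
  handling of any kind.
* The ladder method saturates at DA 15 (its top rung) and is soft below 9;
  cohorts concentrated at those edges will show edge artefacts that are
  properties of the method itself.
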