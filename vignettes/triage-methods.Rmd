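---
title: "Methods: traffic-light triage, oracle validation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: traffic-light triage, oracle validation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anctriage)
```

## The problem this package addresses

In rural primary-care settings, community health workers conduct antenatal
and postnatal home visits for women in the last trimester of pregnancy.
Three conditions dominate the preventable risk in this population: anemia,
hypertensive disorders of pregnancy (HDP), and gestational diabetes
mellitus (GDM). `anctriage` encodes guideline-based screening rules for
these three conditions as a deterministic traffic-light engine — GREEN
(normal), YELLOW (refer), RED (urgent referral) — together with the
validation protocol such rule sets must pass before field deployment, and
a synthetic trial-cohort generator so the whole pipeline is testable
without any patient data.

## The decision model

Every visit contributes up to three classifications.

**Blood pressure and shock index.** The blood-pressure color is the worst
of three criteria: systolic band, diastolic band, and shock-index band,
where the shock index SI = HR/SBP captures hemodynamic compromise (e.g.
postpartum hemorrhage) that normal-looking blood pressure can mask. The
default bands follow the vital-signs-alert device specification used in
obstetric early-warning programs:

| criterion | GREEN | YELLOW | RED |
|---|---|---|---|
| SBP (mmHg) | < 140 | [140, 160) | >= 160 |
| DBP (mmHg) | < 90  | [90, 110)  | >= 110 |
| SI (HR/SBP) | < 0.9 | [0.9, 1.7) | >= 1.7 |

**Hemoglobin.** RED below 7.0 g/dL (severe anemia, urgent), YELLOW in
[7.0, 11.0), GREEN at or above 11.0. Within the YELLOW band, hemoglobin
below 10.0 g/dL — the moderate-to-severe anemia line used as the study
outcome definition — carries a referral-strength recommendation; above it,
counseling advice.

**OGTT.** A nonfasting 75-g load with 2-hour capillary glucose, per the
national GDM screening guideline: GREEN below 140 mg/dL, YELLOW (GDM,
refer) at or above 140, RED (overt diabetes, urgent) at or above 200. A
missing glucose value is a distinct "not screened" outcome, never a
color, and raises a missing-practice prompt instead.

The overall color is the maximum severity among the per-condition colors.
Recommendations are ordered RED items first, then YELLOW, then
missing-practice prompts, stable within severity by condition (BP, Hb,
GDM), so the most urgent action is always first on screen.

All band edges live in `inst/extdata/thresholds.yaml`, with units, loaded
by `load_thresholds()`; the engine refuses a config with any key missing.
The numeric cells were fixed from the guidelines the deployed app cites;
if a deployed screen is found to differ, the YAML — not code — is the
place to correct it.

### Numerical conventions

* Bands are half-open and lower-inclusive; a reading exactly at an edge
  takes the **more severe** color. The boundary-contract tests assert the
  color flip at every edge and one resolution step below it.
* Measurement resolutions: 1 mmHg (BP), 1 bpm (HR), 0.1 g/dL (Hb),
  1 mg/dL (glucose), 0.01 (SI ratio). These drive boundary enrichment and
  the mutation-sensitivity check.
* Severity is monotone in DBP, HR, glucose, in SI, and in SBP *at fixed
  shock index*. At fixed heart rate a rise in SBP lowers the shock index
  and can retire an SI flag — clinically correct, and worth knowing when
  reasoning about the table.
* Shock index is a domain error (never 0 or infinity) when SBP is
  missing or non-positive; classification never silently defaults to
  GREEN.
* Gestational dating is the 280-day rule from the last menstrual period;
  the enrolment window "28 to 36 weeks" is read inclusively as 196–258
  days (28+0 through 36+6). The postpartum week-6 window is delivery +
  36..48 days (42 ± 6; the protocol states "week 6" without tolerance).
* Age is completed years at the reference date, as registered in clinics.

## Two-step validation against an independent oracle

Deployed rule sets of this kind are accepted only after (1) a clinical
fixture of 200 cases covering the full range of scenarios and (2) a
randomly generated set of 10,000 cases, each classified independently by
a second implementation, reach a 100% output match. The original protocol
used a separate SAS program as the second coder; this package takes the
view that the independence that matters is of *control flow*, not vendor:
`oracle_assess()` is a nested exhaustive if/else decision tree written
directly from the threshold config, sharing nothing with the table-driven
engine except that config. Concordance is defined over per-condition
colors, the overall color, and the ordered recommendation *codes* (text
is presentation and excluded).

The sampling distribution of the 10,000-case set is this package's
choice, as the protocol only requires "a wide range of scenarios":
uniform over the full valid record ranges at measurement resolution, with
a 10% per-variable chance of pinning the value exactly to a configured
band edge (for SI, an SBP/HR pair with an exact edge ratio). Boundary
enrichment makes the set sensitive by construction: the mutation check
perturbs each band edge by one resolution step in the oracle's copy of
the config and requires at least one discordance — a discordance-free
mutated run would mean the case set could not detect a one-step
transcription error, the failure mode this protocol exists to catch.

The "iterate until 100%" clause is realized as a gate: the test suite
asserts `match_fraction == 1` on both steps, and the `validate` CLI exits
non-zero below 100%.

## The synthetic cohort: a stated world

`simulate_cohort()` emulates the pilot two-arm cluster trial the package
is designed around: 100 women per arm across four facility clusters (two
states, one intervention and one control facility each), enrolled in the
last trimester, with an antenatal visit at registration and postpartum
visits at delivery + 3 and + 42 days. The defaults in
`default_sim_config()` *are* the published trial's values — baseline and
end-line moments for age, BMI, schooling, household size, hemoglobin and
blood pressure per arm; 47/100 and 58/100 baseline anemia; 5/200 HDP and
4/200 GDM cases; 163/200 screened for GDM and 37/200 with a prior OGTT;
4 control-arm women (two per state) lost to follow-up; 100% visit
fidelity; per-cluster recruitment windows spanning the reported 50–128
days.

Two generation principles:

* **Moments are approximate, counts are exact.** Continuous variables are
  drawn from truncated normals at the configured moments. Dichotomized
  quantities are enforced exactly by rank-based assignment: e.g. baseline
  hemoglobin is affinely shifted so that exactly the configured number of
  lowest-Hb women fall below 10.0 g/dL, then the straddling values are
  clamped to the correct side after rounding. Proportions downstream
  therefore recompute to the printed numerator/denominator pairs exactly,
  which is what the worked examples and tests assert. The cost is a small
  systematic shift in the baseline-Hb mean (about +0.2 g/dL at the
  default configuration, inside the 3-standard-error recovery band the
  tests allow).
* **Labels agree with the rules engine.** HDP and GDM cases are assigned
  measurement values inside the YELLOW bands and everyone else strictly
  inside GREEN (including the SI criterion), so prevalence recomputed
  through the engine equals the configured counts.

Values the source trial does not report were chosen once as realistic and
are not tuned: resting heart rate 82 (SD 10) bpm truncated below the SI
YELLOW edge; maternal height 1.56 (SD 0.06) m with weight back-computed
from BMI; iron-folic-acid supply flags for 90/100 per arm; delivery at
280 (SD 8) days truncated to 262–292; the study-wide HDP 5 and GDM 4
split 2/3 and 2/2 across arms (the source reports only totals; both
prevalences are computed over both arms, so the split is presentational).
An optional `endline_gap` flag reproduces the pandemic-era loss of
end-line measurements (78/62 end-line records); it is off by default.

What a green test on this cohort does **not** establish: the generator
assumes independence between variables (no joint distribution is
published), no cluster-level random effects or intraclass correlation, no
care-seeking behavior, and postpartum blood pressure and glucose that
have normalized in all non-case women. The end-line hemoglobin contrast
between arms is whatever the configured moments imply — reproducing the
real trial's end-line difference and its p-value would require the raw
data and is deliberately not an acceptance claim.

## Summary statistics

`trial_summary()` recomputes the feasibility surface: per-cluster
recruitment days and monthly rate (30.44-day months), retention,
fidelity (scheduled visit entries present, complete and on time),
prevalence of the three conditions (operationalized as ≥ YELLOW through
the rules engine, since no separate diagnostic algorithm is published),
screening coverage, and the arm-comparison table. The two-sample
comparison is Welch's unequal-variance t-test — the source publication
prints p-values without naming a test, and Welch is the conservative
default; the choice is isolated in one internal function (`welch_p`) so a
pooled-variance variant is a one-line swap. Display conventions follow
clinical-table practice: 1 decimal for means/SDs, p to 2 decimals with
`>.99` for near-1 values and `NC` when variance is degenerate, and
half-up rounding for whole-percent displays (R's default half-even
rounding would print 18.5% as 18%).

## Known limitations

* Thresholds were reconstructed from the cited guidelines, not read off
  the deployed app's screens; the YAML config is the reconciliation
  point.
* Amber and yellow are collapsed into a single YELLOW level.
* The cohort simulator is a stated world for testing the pipeline, not an
  epidemiological model; see above for what it omits.
* Cluster-adjusted inference, ICC estimation and sample-size planning for
  a definitive trial are out of scope.
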