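---
title: "Methods: fever-exposure analysis of caregiver-entered records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fever-exposure analysis of caregiver-entered records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feverpghd)
```

`feverpghd` compares fever reduction between single- and
combination-antipyretic regimens in home-collected fever diaries. This
vignette is the package's account of the underlying model, the choices
behind every tunable parameter, what the synthetic-data generator does and
does not emulate, and the numerical conventions a reader needs to
interpret the outputs.

## The measurement model and its assumptions

Caregiver diaries record temperature at irregular times. The pipeline's
central assumption is that temperature varies approximately linearly
between two nearby readings, so the unobserved trace can be recovered by
linear imputation. Everything downstream is built on that interpolant:

* **Episodes** are maximal intervals where the interpolant is at or above
  the fever threshold (default 38.0 ℃). Onset and offset are the
  interpolated crossing times, which makes episode duration well defined
  even when readings are sparse. Ties at exactly the threshold count as
  febrile. A reading sequence that ends febrile yields an *unresolved*
  episode: its duration is unknown (caregivers often stop logging once
  the child improves), so resolved and unresolved episodes are reported
  separately and only resolved durations enter summary statistics.
* **Cases** — the unit of analysis — are 72-hour windows opened by the
  first unassigned dose, with a half-open boundary: a dose at exactly
  +72 h opens the next case. The half-open convention is a deterministic
  tie-break; windows never overlap, and every dose belongs to exactly one
  case.
* **Baseline** is the interpolated temperature at the first
  administration. When the anchor lies just outside the observed span the
  nearest reading within 1 h substitutes; beyond that the case is flagged
  baseline-missing and excluded from AUC analyses (but still counted and
  classified).
* **Fever exposure** is the trapezoidal integral of the hourly-sampled
  temperature change from baseline over 6/8/10/12-hour horizons, in ℃·h.
  Horizons are additive by construction
  (`AUC(0→12) = AUC(0→6) + AUC(6→12)` on the shared grid). Cases whose
  series ends before a horizon are flagged truncated and excluded from
  that horizon's comparison — imputing beyond the last reading would
  require extrapolation, which the package never does.

## Statistical conventions

Group comparisons use the pooled-variance Student *t* test computed from
summary statistics (the form that also works on published tables), the
Pearson chi-square without continuity correction for proportions, and
standardized effect sizes: Cohen's *d* for means and Cohen's *h*
(arcsine difference) for proportions. Two *d* poolings are offered; the
default is the equal-weight form `sqrt((s1^2 + s2^2)/2)`, which is the
variant that reproduces the published worked-example values shipped in
the reference tables; the sample-size-weighted pooling is available via
`cohen_d_variant = "n_weighted"`. "Total" columns are mixture moments of
the group rows (`var = sum w_i (s_i^2 + m_i^2) - m^2`), which is exact
for population variances and indistinguishable from pooling at the table
sizes involved. No multiplicity adjustment is applied: the tables mirror
the descriptive-comparison style of the field, where p-values accompany
each row individually.

Degenerate inputs follow fixed conventions: zero pooled variance gives
`t = 0` (equal means) or a signed infinite statistic with `p = 0`; a
group with fewer than two observations yields `NA` statistics rather
than an error; empty onset bins have `NA` percentages.

## The synthetic cohort generator

The generator exists so that episode segmentation, case construction,
AUC estimation and the group statistics can be validated against known
truth. Each child gets a latent fever course

> baseline `B` + peak `P` · (logistic rise to the peak time, exponential
> decay afterwards) + one additive drug kernel per dose,

with every piece analytically integrable (softplus, exponential and
trapezoid terms), so the generator can emit the *exact* baseline-anchored
AUC for every simulated case (`course_auc_true()`). The drug kernel is
piecewise linear — flat for `lag_h` (default 0.5 h), descending to
`-nadir_drop_c` at `nadir_h` (2 h), recovering to zero by
`effect_duration_h` (6 h) — a phenomenological shape chosen for the
observed ~2-hour nadir and ~6-hour washout of antipyretics, not a
pharmacokinetic model.

Caregiver behaviour is modelled per child (threshold, combination
propensity, ingredient preference), which reproduces the case-level
clustering real diaries show:

* **Dosing trigger.** A caregiver threshold ~ N(38.3, 0.3) truncated to
  ≥ 38 ℃, plus an exponential reaction delay (mean 2 h, capped at 8 h)
  during which the fever keeps rising. The delay is what spreads onset
  temperatures above the threshold: it reproduces both the published
  onset-band distribution (roughly 0.2/5/67/25/2 % across
  <37, [37,38), [38,39), [39,40), ≥40 ℃) and the small observed gap
  between mean baseline and mean maximum temperature. A threshold
  distribution alone cannot do this without making dosing almost always
  coincide with 38.3 ℃.
* **Early dosers.** A caregiver fraction (default 0.115) doses below
  38 ℃ (threshold ~ N(37.6, 0.35) truncated below 38). After the
  reaction delay and measurement noise around the 38.0 boundary, this
  calibrates the *measured* under-38 first-dose share to ≈ 5.5 %.
* **Regimen.** The probability of a combination regimen increases with
  the onset-temperature band (defaults 0.13 / 0.19 / 0.238 / 0.345 /
  0.414, matching the published monotone gradient) and is resolved
  against a single per-child propensity. Combination caregivers
  alternate ingredients at 4–6 h intervals with the second dose given on
  schedule (alternating regimens are schedule-driven in practice); this
  also guarantees a combination case shows at least two ingredients, so
  the pipeline's observed label equals the policy. Single-agent
  caregivers re-dose at threshold re-crossings at least 4 h apart.
* **Measurements.** An inhomogeneous sampling process with intensity
  `0.25 + 0.8 · max(0, T − 37.5)` per hour — caregivers measure more
  when the child is hot — plus a reading at each dose and a re-check
  1–2.5 h after it. Observations add N(0, 0.1 ℃) noise and are
  quantised to 0.1 ℃ and minute resolution.

Identical `(config, seed)` pairs reproduce the cohort byte-for-byte
through the CSV writers.

### What the generator does not emulate

No circadian rhythm, no multi-peak fevers, no pharmacokinetic
accumulation or interaction, no dose-size errors, no site/method
measurement offsets, and no informative drop-out of entire children.
Consequently, passing the validation suite demonstrates that the
*pipeline* is correct and calibrated under realistic irregular sampling —
not that real single/combination effect estimates are unconfounded. In
particular, the generator's default fever decay (30 h time constant) is
chosen to match observed fever *durations* (~25 h), which makes synthetic
AUC magnitudes (≈ −2 ℃·h at 6 h) smaller than those reported for real
cohorts (≈ −3.7 ℃·h); real fevers fall faster early while lasting long,
a shape a single exponential cannot reproduce. None of the validation
checks depends on matching those magnitudes.

## Validation design and problem sizes

The suite validates every stage against an independent route:

* **Interpolation/episodes**: a brute-force 1-minute classification of
  the interpolant over 1,000 random irregular series; analytic crossing
  endpoints must agree to the grid's resolution (features narrower than
  one minute are below the oracle's resolution by construction, on both
  sides — sub-minute episodes and sub-minute dips).
* **AUC**: 1,000 random cases compare the hourly trapezoid against a
  1-minute Riemann sum of the same hourly polyline, within the Riemann
  discretization bound; horizon additivity holds to 1e-9.
* **Null calibration**: 500 replicate cohorts with identical kernels and
  an identical dosing rule for both regimens (always-redosing caregivers
  on a fixed 4-h rhythm), making the group label pure relabelling; the
  6-h AUC *t* test must reject at 0.05 within two binomial standard
  errors. An earlier design with temperature-conditional re-dosing
  demonstrated how observed-label conditioning can silently break such
  nulls: combination cases that happened to show only one ingredient
  migrated to the single group, carrying a real dose-count difference
  with them.
* **Parameter recovery**: a 6,000-child cohort (≈ 9,000 cases, fixed
  seed) in which pipeline group means of the 6-h AUC must land within
  3 SE of the exact closed-form ground truth, and combination shares per
  onset band within 2 percentage points of the configured
  probabilities. The share check is asserted on bands holding at least
  1,000 cases: under the published band masses the <37 band carries
  ~0.2 % and the ≥40 band ~2 % of cases, so a 2-point tolerance is below
  binomial noise there at any cohort size this suite could run.

These sizes keep the whole suite within a few minutes while leaving all
binomial/normal tolerances comfortably above their standard errors.

## Known limitations

Linear imputation across long reporting gaps is biologically implausible;
a configurable maximum-imputation gap (`max_gap_h`, default off,
suggested 12 h) splits series at such gaps, at the cost of more
unresolved episodes. Baselines taken at the first dose inherit that
reading's measurement noise, which propagates into every AUC of the case
(± ~0.6 ℃·h at 6 h); it is unbiased but widens group SDs. Unresolved
episodes make mean fever duration an underestimate of the true episode
length distribution. And because regimen choice in real diaries is
behaviourally confounded with fever severity, between-group AUC contrasts
on observational data are descriptive, not causal — the package reports
effect sizes, not treatment effects.
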