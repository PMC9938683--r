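---
title: "Methods: the MVPA timing phenotype and its survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MVPA timing phenotype and its survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoactivity)
```

## The problem this package addresses

Wrist accelerometry records a week of free-living movement as average
vector-magnitude acceleration (in milligravity, mg) per 5-second epoch. From
such traces one can ask not only *how much* moderate-to-vigorous physical
activity (MVPA) a person accumulates, but *when* in the day they accumulate
it, and whether that timing carries prognostic information for mortality
beyond total volume. `chronoactivity` implements the full chain from raw
epoch series to a four-level diurnal timing phenotype — morning
(05:00–11:00), midday-afternoon (11:00–17:00), evening (17:00–24:00), or
mixed — and the survival machinery used to relate that phenotype to
all-cause and cause-specific mortality.

Because individual-level accelerometer cohorts of this kind are
controlled-access, the package ships a synthetic-data generator with known
ground truth (timing archetypes and planted hazard ratios). Every stage is
therefore exercisable and testable at desk scale, and the survival stage can
be validated by parameter recovery rather than by re-analysis of restricted
data.

## Epoch processing

**Non-wear detection.** Device-off time is inferred from prolonged
stationarity: a sliding 1-h window (720 epochs) is moved over the trace, and
every epoch covered by a window whose sample standard deviation of vector
magnitude falls below 13.0 mg is flagged non-wear. The union of flagged
windows forms maximal stationary runs of at least one hour by construction.
The 13.0 mg / 1 h parameters are the conventional wrist-accelerometer
stationarity rule; the original rule is stated per axis on raw data, and
since this package models only epoch-level vector magnitude, the same
threshold is applied to the windowed SD of vector magnitude. A brute-force
window scan is kept in the test suite as an oracle for the vectorized
implementation.

**Imputation.** Each non-wear epoch is replaced by the mean of wear-epoch
values at the *identical 5-s clock slot* on the other recorded days. Whether
the slot should be the exact 5-s position or a coarser bin is not decidable
from published descriptions; the exact slot is the default and an
hour-resolution pooling is available via `resolution = "hour"`. A clock slot
that is non-wear on every day is an error naming the slot — such a
participant should fail quality control instead.

**Quality control.** A trace is valid when it carries at least 72 h of wear
and every 1-h clock bin of the 24-h cycle is covered by wear at least once.

## MVPA quantification

Moderate activity is sessionized: a clock-aligned, disjoint 5-min block is a
moderate session when strictly more than 80% of its sixty epochs lie in the
closed range 100–400 mg. Disjoint clock-aligned blocks (rather than a
sliding window) avoid double counting and make the rule deterministic; a
sliding variant cannot be ruled out from published descriptions, which is
why the block convention is stated here explicitly. Vigorous activity is any
epoch strictly above 400 mg; the two definitions partition at 400 mg with
the boundary belonging to moderate. Vigorous epochs inside a detected
session are not double counted.

Daily MVPA minutes sum 5 min per session starting in 05:00–24:00 plus 5/60
min per standalone vigorous epoch in that window; activity between midnight
and 05:00 contributes nothing to the daily totals (but is kept in the 24-h
histogram for the nocturnal filter). Weekly MVPA is extrapolated as
`sum(daily) / valid_days * 7`, where a day is valid with at least 16 h of
wear (a conventional choice; the QC criteria already guarantee 72 h
overall). Each MVPA minute is attributed to the clock hour containing its
midpoint, yielding the 24-bin histogram that feeds the timing phenotype.

## The timing phenotype

Window fractions are computed from the pooled whole-week histogram — minutes
in each window divided by total 05:00–24:00 minutes — rather than per day
and then averaged; pooling is robust to sparse days and matches the notion
of total weekly MVPA share. A participant is assigned to a window when its
fraction reaches the cutoff (default 0.50; sensitivity cutoffs 0.55–0.70),
and to the mixed group otherwise. A tie at the 0.50 cutoff goes to mixed,
the "no dominant window" category by definition. Zero-MVPA participants get
undefined fractions and are routed to a zero-MVPA stratum, never silently
labelled mixed.

The nocturnal exclusion removes participants with more than 10% of activity
accumulated between 01:00 and 04:00. "Activity" is measured by default as
acceleration-weighted volume (per-hour sum of vector magnitude), because
nocturnal MVPA minutes are typically zero and an MVPA-based filter would
almost never fire; `measure = "mvpa"` switches to MVPA minutes.

## Window discovery

The three analysis windows are not assumed; they are recovered by an
outcome-based scan. Participants are assigned to 2-h small-window groups
(3-h for 21:00–24:00) under a strict >50% rule, each group is contrasted
against the mixed reference in a Cox model, and a window is *elevated* when
its point hazard ratio exceeds 1. Change points are the grid boundaries
where the elevated flag flips between consecutive windows. The point
estimate (not the confidence interval) defines the flag because the
discovery step is descriptive, not inferential; a CI-based flag is available
(`ci_based = TRUE`), as is an optional intersection across outcomes.
No formal change-point test statistic is attached; the flip rule is this
package's explicit operationalization of an otherwise qualitative procedure.

In the scan simulations the six 2-h groups inside 05:00–11:00 and
17:00–24:00 carry a planted hazard ratio of 1.35 versus mixed (the magnitude
of the morning-vs-mixed CVD contrast implied by the planted group effects)
and the three midday groups carry 0.85. The midday value sits deliberately
*below* 1 rather than at 1: under the point-estimate flip rule a window with
a true HR of exactly 1 would be flagged elevated with probability one half
regardless of sample size, so "not elevated" must be encoded as a hazard
decisively below the reference for boundary recovery to converge. With
these conditions the scan recovers exactly {11:00, 17:00} in well over 90%
of replicates at n = 50,000.

## Cohort assembly

Exclusions apply in a frozen order — withdrawal, incomplete hourly coverage,
nocturnal activity, invalid accelerometry — with each participant counted
once at the first criterion that removes them; the ledger counts sum exactly
to initial minus final n, and the order sensitivity is tested. The healthy
diet score counts five satisfied dietary criteria (vegetables, fruit, fish,
limited unprocessed red meat, limited processed meat).

Missing covariates are handled by a *single* seeded stochastic imputation:
categorical values (including integer-coded scores) are drawn from observed
class frequencies, continuous values from a linear regression on the
complete covariates plus Gaussian noise at the residual scale. This is a
deliberate simplification of chained-equations multiple imputation with
pooling — the estimand here is the method chain, not imputation variance,
and a complete-case mode mirrors the no-imputation sensitivity analysis.
The imputation model uses all complete covariates as predictors, stated
explicitly since no canonical predictor list exists for this step.

## Survival analysis

Three nested Cox models (Efron tie handling, as is standard; ties are
measure-zero under the exponential generator anyway) adjust for: (1) age and
sex; (2) plus ethnicity, deprivation, region, education, wear season, diet
score, smoking, alcohol; (3) plus sleep duration, sleep midpoint, and total
weekly MVPA volume. Hazard ratios are reported per group against the
morning reference with events and person-years.

**Dose-response.** Continuous exposures (weekly MVPA, window MVPA minutes
with mutual adjustment for the other windows, window fractions with
adjustment for total volume) enter through `survival::pspline()` with a
target of 4 effective degrees of freedom — a smoothness choice comparable to
a 4-knot natural spline, configurable and logged since no canonical value
exists. `P_overall` is a likelihood-ratio test of all spline terms against
the covariates-only model, `P_nonlinear` an LRT of the spline against a
linear exposure term, each on the spline's effective degrees of freedom
(the test is not canonical; an LRT is the natural choice and is stated
explicitly). Exposures are winsorized at 750 min/week by default. The HR
curve is the spline term centered at the reference exposure (median by
default, so HR = 1 there) with the term's pointwise standard errors.

**Standardized risk.** Cumulative-incidence curves per timing group use
G-computation: the fitted model predicts every participant's cumulative
incidence with the group forced to each level in turn, and the predictions
are averaged over the whole cohort's covariate distribution. Direct
standardization over an external population would be the main alternative;
G-computation was chosen because it uses the analysis cohort itself as the
standard and needs no extra inputs.

**Competing risks.** Fine-Gray subdistribution hazards (via `cmprsk::crr`)
treat other-cause death as the competing event. In the no-competing-event
limit the subdistribution risk sets coincide with the cause-specific ones,
and the test suite verifies agreement with the Cox coefficients to 1e-6.

**Multiplicity.** The FDR family is the set of fully adjusted timing
contrasts across the outcome tables, corrected by Benjamini–Hochberg.

**Interaction.** For interaction and subgroup analyses the four groups are
dichotomized into unfavorable (morning/evening) versus favorable
(midday-afternoon/mixed) timing. Multiplicative interaction is the Wald test
of the product term; additive interaction uses the standard relative-excess
definitions, RERI = HR11 − HR10 − HR01 + 1, AP = RERI/HR11,
SI = (HR11 − 1)/((HR10 − 1) + (HR01 − 1)), with delta-method confidence
intervals (log scale for SI, which is reported as undefined when its
denominator vanishes). The delta method is assumed for the CIs since no
exact convention is canonical for these measures.

## The synthetic generator: what it emulates and what it does not

Generation is two-tier because 7 days × 17,280 epochs × 50,000 participants
is not desk-scale:

* **Tier 1 (epoch level, up to 10,000 participants)** builds full 7-day
  traces: a sedentary daytime baseline with movement bursts, near-rest
  nights with posture-shift spikes, moderate sessions placed as clock-aligned
  5-min blocks so that the archetype window holds a configurable
  concentration (default 0.8) of MVPA, sparse vigorous epochs, Poisson
  non-wear episodes of 1.2–3 h of near-constant low signal placed in
  daytime, and optional nocturnal-outlier participants with sustained
  01:30–02:30 activity. Mixed-archetype MVPA is cycled through the three
  windows so no window can dominate. The within-window placement templates
  are invented — no distributional description of real within-window MVPA
  placement exists to copy — and that is exactly why the recovery tests
  condition on the planted truth rather than on realism of placement.
* **Tier 2 (phenotype level)** draws the timing group, group-consistent
  window fractions (dominant fraction uniform on [0.5, 0.95]; mixed
  fractions Dirichlet(5,5,5) rejection-sampled below 0.5), weekly MVPA
  log-normal with median 113.83 min/week and sdlog 0.9655 (chosen so the
  IQR is 158.67 min/week), and covariates matching the emulated cohort's
  marginal baseline table. Covariate effects on the hazard default to zero
  to isolate timing-group recovery.

Survival is exponential per cause with administrative censoring at 7.0
years (the emulated median follow-up), so proportional hazards hold exactly
and every planted log hazard ratio is a known truth. Default baseline
hazards give roughly 1.17% CVD, 2.03% cancer, and 0.15% other-cause deaths
over follow-up (about 3.3% all-cause); `all_cause_config()` collapses this
to a single all-cause process. The time axis is local clock time with no
daylight-saving transitions — DST handling in real data is a flag
pass-through, not something the generator simulates. Not emulated: raw
100 Hz signal structure, seasonal activity variation, correlated covariate
structure, non-proportional hazards, and informative censoring. Passing
recovery tests therefore demonstrate correctness of the estimation chain
under the stated model, not robustness to real-data violations of it.

## Numerical and degenerate-input conventions

* Stationarity uses the sample SD over exactly one window length; runs
  shorter than the trace emit a warning and an all-wear mask.
* Sessions at exactly 80% in-range are *not* sessions (strict inequality);
  epochs at exactly 400 mg are moderate, not vigorous; a nocturnal share of
  exactly 10% is kept (strict >).
* Ties at the group cutoff go to mixed; zero-MVPA fractions are `NA`.
* Zero-event windows in the scan are flagged unstable and skipped when
  locating flips.
* `crr` is run with `gtol = 1e-10` so the no-competing-risk limit matches
  Cox coefficients to 1e-6.
* Exclusion flags absent from a cohort default to "not excluded".

## Problem sizes used by the shipped experiments

The packaged tests and the acceptance script run: planted-recovery fits at
n = 50,000 with ~1% (CVD-pattern) and ~3.3% (all-cause-pattern) event
proportions, averaged over 16 replicates in the acceptance script; 20
window-scan replicates at n = 50,000; 200 epoch-level participants for the
phenotyping oracle checks at concentration 0.7; 200 global-null replicates
at n = 5,000 (12 fully adjusted contrasts each) for FDR calibration. These
sizes keep each experiment in the seconds-to-minutes range on a single CPU
while leaving Monte Carlo error well inside the asserted tolerances.

## Known limitations

* The dose-response curve's confidence band uses the spline term's pointwise
  standard errors (termplot convention), not the full covariance against the
  reference point; bands very near the reference are conservative.
* The 2-h scan's elevated rule is a point-estimate sign rule by design;
  with truly null windows its flip locations are noise (see the window
  discovery section).
* Single imputation understates imputation uncertainty relative to pooled
  multiple imputation; standard errors for heavily imputed covariates are
  slightly optimistic.
* The generator's independence assumptions (covariates independent of
  timing group) make confounding adjustment exercises structural rather than
  realistic; planted covariate effects can be switched on via
  `covariate_log_hr` when correlated stress tests are wanted.
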