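# chronoactivity

Timing-of-activity phenotyping and mortality analysis from wrist
accelerometry.

## What problem this solves, and for whom

Epidemiologists working with week-long wrist-accelerometer cohorts can
measure not just how much moderate-to-vigorous physical activity (MVPA)
people do, but *when* in the day they do it. This package implements, as a
tested and reusable pipeline, the full chain from 5-second epoch
vector-magnitude traces (in milligravity) to a four-level diurnal MVPA
timing phenotype, and the survival analysis relating that phenotype to
all-cause and cause-specific mortality:

1. **Epoch processing** — non-wear detection (stationary episodes ≥ 1 h with
   windowed SD < 13 mg), similar-time-of-day imputation, wear-time QC
   (≥ 72 h and all 24 hourly bins covered).
2. **MVPA quantification** — moderate sessions (5-min blocks with > 80% of
   epochs in 100–400 mg), vigorous epochs (> 400 mg), daily 05:00–24:00
   minutes, 7-day extrapolation, hour-of-day histogram.
3. **Timing phenotype** — window fractions over morning (05–11),
   midday-afternoon (11–17) and evening (17–24); group = the window holding
   ≥ 50% of MVPA (configurable cutoff 0.50–0.70), else *mixed*; nocturnal
   exclusion (> 10% of activity in 01:00–04:00).
4. **Window discovery** — the outcome-based 2-h grid scan: per-window Cox
   hazards versus the mixed reference, with change points where the
   elevated flag (HR > 1) flips.
5. **Cohort assembly** — ordered exclusions with a conservation-checked
   ledger, healthy diet score, single seeded covariate imputation with a
   complete-case mode.
6. **Survival analysis** — three nested Cox models
   (HR = exp(β) from the partial likelihood, Efron ties); penalized cubic
   spline dose-response with P_overall and P_non-linear (likelihood-ratio
   tests on the spline's effective df); G-computation standardized
   cumulative-incidence curves; Fine-Gray subdistribution hazards under
   competing risks; Benjamini–Hochberg FDR; multiplicative interaction plus
   additive-interaction measures
   RERI = HR₁₁ − HR₁₀ − HR₀₁ + 1, AP = RERI/HR₁₁,
   SI = (HR₁₁ − 1)/((HR₁₀ − 1) + (HR₀₁ − 1)) with delta-method CIs;
   subgroup analyses of the favorable-timing contrast.

Because real cohorts of this kind are controlled-access, a two-tier
synthetic generator with known ground truth (timing archetypes, planted
cause-specific exponential hazards) replaces the data: epoch-level traces
for phenotyping tests, phenotype-level cohorts for survival-scale
experiments. Every planted parameter is recoverable, so the estimation
chain is validated by parameter recovery.

## Worked example

Simulate a 50,000-participant cohort whose cardiovascular-mortality hazards
are planted at 0.72 (midday-afternoon), 0.87 (evening) and 0.74 (mixed)
versus morning, then recover them with the fully adjusted Cox model:

```r
library(chronoactivity)

cfg    <- simulation_config(n_participants = 50000, seed = 42)
sim    <- generate_phenotype_cohort(cfg)
cohort <- generate_survival(sim$cohort, cfg)
fit_timing_cox(cohort, "cvd", model = 3)
#>   outcome group            events person_years    hr ci_low ci_high        p
#> 1 cvd     morning             104       59619. 1     NA      NA     NA
#> 2 cvd     midday_afternoon    188      153384. 0.700  0.551   0.889  0.00348
#> 3 cvd     evening              46       31627. 0.836  0.591   1.18   0.311
#> 4 cvd     mixed               124       99975. 0.709  0.546   0.920  0.00977
```

Each recovered hazard ratio sits within its 95% CI of the planted value:
the midday-afternoon and mixed groups show ~30% lower cardiovascular
mortality hazard than the morning group, the evening group is statistically
indistinguishable from it, and events/person-years are reported per group.

The epoch-level tier exercises the full phenotyping chain:

```r
ep   <- generate_epoch_cohort(simulation_config(n_participants = 2, seed = 5), 2)
s    <- ep$series[[1]]
s
#> <epoch_series> participant P00001: 120960 epochs (168.0 h), 168.0 h wear
prof <- activity_profile(impute_nonwear(s, detect_nonwear(s)))
timing_assignment(prof)
#> <timing_assignment> group midday_afternoon (cutoff 0.50);
#>   fractions morning=0.04, midday_afternoon=0.94, evening=0.02
```

And the exploratory 2-h window scan recovers the boundaries of the elevated
morning/evening hazard pattern:

```r
sc <- generate_window_scan_cohort(n = 50000, seed = 9)
identify_change_points(scan_windows(sc$cohort, model = 1))
#> [1] 11 17
```

The pipeline wrapper `run_pipeline(config, output_dir)` chains
simulate → phenotype → assemble → analyze → report, writing delimited-text
outputs, a plain-text report, and a JSON manifest with file digests.

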