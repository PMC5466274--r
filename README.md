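# solestrike

Footstrike pattern detection from insole sensor onset timing.

## The problem

How a runner's foot first meets the ground — rearfoot (RFS), midfoot (MFS)
or forefoot strike (FFS) — matters for injury prevention and gait
retraining, but the laboratory reference measure requires a force platform.
That reference is the **strike index (SI)**: the position of the centre of
pressure (COP) at initial contact along the foot's long axis, as a
percentage of foot length (0% = heel tip, 100% = toe), with RFS defined by
SI 0–33%, MFS by 34–66% and FFS by 67–100%.

A far cheaper surrogate is a pair of force-sensing resistors in the insole,
one under the heel and one under the second toe. The **onset-time
difference (OTD)** between the two channels,

```
OTD = t_heel − t_toe   (ms; negative when the heel sensor fires first)
```

after linear correction to a 23 cm standard foot length, tracks SI through
a univariate agreement line per running surface:

```
SI = B · OTD + intercept + ε
```

Inverting a fitted line at the 33% and 66% SI class boundaries yields a
pair of OTD cutoffs — a classification *time window* — so an instrumented
insole can label every step RFS/MFS/FFS without a force platform.
Confidence bounds on the cutoffs follow from the 95% CI of `B` with the
intercept held fixed. The windows differ materially between level, uphill
(+10°) and downhill (−10°) running, so the package keeps surface-stratified
models throughout.

`solestrike` implements the whole chain in tidyverse style — tibbles in and
out, `tidy()`/`glance()` accessors, `autoplot()` — plus a seeded
synthetic-gait generator that emulates the reference study design (109
subjects × 3 surfaces × 3 instructed patterns × 30 footfalls on a
split-belt treadmill, with ~12.8% of landings lost on the belt split), so
every stage is testable end to end without any instrument data:

* signal layer: zero-phase 4th-order Butterworth low-pass at 50 Hz
  (`lowpass_filter()`), stance segmentation by a 10 N vertical-GRF
  threshold (`segment_stances()`), last-30-footfall extraction
  (`keep_last_n()`), split-belt exclusion (`exclude_split_belt()`);
* measurement layer: `compute_si()`, `detect_onset()`, `compute_otd()`,
  `normalize_otd()`, tied together by `process_traces()`;
* statistics layer: `fit_si_on_otd()`, `derive_cutoffs()`, `predict_si()`,
  `classify_si()` / `classify_otd()`, `agreement_report()`;
* the published reference calibration, available offline via
  `reference_lines()`;
* simulation: `population_spec()`, `simulate_footfalls()`,
  `simulate_traces()`, `simulate_trial()`;
* batch stages with config echo: `run_simulate()`, `run_process()`,
  `run_analyze()`, `run_classify()`, and a thin CLI at
  `inst/cli/solestrike.R` (`simulate | process | analyze | classify`).

## Worked example

Simulate the full study design, fit the level-surface agreement model,
derive its classification window, and score the insole labels against the
force-platform labels:

```r
library(solestrike)

spec <- population_spec(n_subjects = 109, seed = 2026)
footfalls <- simulate_footfalls(spec)   # 29,430 rows

fit <- fit_si_on_otd(footfalls, scope = "flat")
fit
#> <si_otd_fit> scope: flat
#>   SI = 0.439 * OTD + 42.50   (R^2 = 0.837)
#>   B = 0.439 (95% CI 0.435-0.443), t = 209.37, beta = 0.915, VIF = 1, p <0.001, n = 8542

derive_cutoffs(fit)
#> # A tibble: 2 × 5
#>   scope si_target   otd ci_lower ci_upper
#>   <chr>     <dbl> <dbl>    <dbl>    <dbl>
#> 1 flat         33 -21.6    -21.8    -21.4
#> 2 flat         66  53.5     54.0     53.0

analyzed <- dplyr::filter(footfalls, !split_belt, surface == "flat")
agreement_report(
  classify_si(analyzed$si),
  classify_otd(analyzed$otd_norm, derive_cutoffs(fit)))
#> <agreement_report> n = 8542, overall agreement = 82.6%
#>      otd
#> si     RFS  MFS  FFS
#>   RFS 2114  198    0
#>   MFS  548 2690  501
#>   FFS    0  242 2249
#> per-class recall: RFS 91.4%, MFS 71.9%, FFS 90.3%
```

Reading the output: the fitted line says each extra millisecond of OTD
(toe onset later relative to heel) raises the expected strike index by
0.44 percentage points; OTD alone explains ~84% of SI variance on the
level surface. A footfall whose normalised OTD is below −21.6 ms is called
a rearfoot strike, above 53.5 ms a forefoot strike. Misclassifications
concentrate in the midfoot band, as expected for thresholds on a noisy
continuous surrogate.

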