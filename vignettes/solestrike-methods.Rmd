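---
title: "Methods: strike index, onset-time differences, and classification windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strike index, onset-time differences, and classification windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

The strike index (SI) — the centre-of-pressure (COP) position at initial
contact, as a percentage of foot length — is the laboratory criterion for
footstrike pattern, but it needs a force platform. A two-sensor insole
(force-sensing resistors under the heel and the second toe) offers a
surrogate: the onset-time difference

$$\mathrm{OTD} = t_{\mathrm{heel}} - t_{\mathrm{toe}} \quad [\mathrm{ms}],$$

negative when the heel sensor fires first. `solestrike` implements the
agreement model linking the two,

$$\mathrm{SI} = B \cdot \mathrm{OTD} + c + \varepsilon,$$

fitted by ordinary least squares per running surface, and its inversion
into classification time windows: the OTD values at which the fitted line
crosses the 33% and 66% SI class boundaries separating rearfoot (RFS),
midfoot (MFS) and forefoot (FFS) strikes.

Model assumptions, stated plainly: (i) within a surface, the conditional
mean of SI given OTD is linear over the observed OTD range; (ii) residual
scatter is homoscedastic and approximately Gaussian; (iii) footfalls are
treated as exchangeable — repeated measures within subject are pooled, not
modelled hierarchically. Assumption (iii) follows the reference analysis;
a mixed model would widen the slope CI but not move the point estimates
materially for a balanced design.

## The processing chain and its tunables

All defaults live in `run_config()` and are echoed into every output's
metadata, so a run is reproducible from its own files.

* **Low-pass filter**: 4th-order Butterworth, 50 Hz cutoff, applied
  forward and backward (zero phase). Zero-phase filtering is the gait
  convention because event *timing* is the quantity of interest; the cost
  is a squared magnitude response (gain 0.5 at the cutoff instead of
  −3 dB). A single causal pass is available via `zero_phase = FALSE`.
  Numerically, the implementation pads the signal by odd reflection over
  roughly `3 · order · fs / cutoff` samples before the forward-backward
  pass: the filter state is otherwise zero-initialised, and the settling
  transient scales with the cutoff period, not the filter order.
* **Contact threshold**: 10 N on the filtered vertical GRF, a conventional
  force-plate contact criterion. Stances shorter than 50 ms are discarded
  as noise; an episode still loaded at the end of a recording is dropped
  as incomplete.
* **Steady-state extraction**: the last 30 footfalls of a trial are kept
  (`n_last_footfalls`), then split-belt landings are flagged. The order
  matters for the bookkeeping: the collected count is last-30 × conditions,
  and exclusion happens at analysis time, which reproduces the
  collected/excluded/analysed accounting of the reference design. Flagged
  rows are retained in the record table (`split_belt = TRUE`) and dropped
  by `fit_si_on_otd()`.
* **Split zone**: landings with |lateral COP| ≤ 1 cm of the belt-split
  midline are unusable (the COP straddles two plates). The physical gap
  width is hardware-specific; 1 cm is a deliberate, configurable default.
* **Onset detection**: first sample at or above 10% of the channel
  maximum within the stance window. A relative threshold is used because
  FSR output is uncalibrated; an absolute level would need per-sensor
  tuning. The onset window opens 20 ms before the force-plate contact
  sample because a forefoot landing triggers the toe sensor at true
  contact, fractionally before the 10 N force crossing.
* **OTD normalisation**: multiply by `23 / foot_length`
  (`mode = "to_standard"`), mapping each subject onto a 23 cm standard
  foot — a longer foot rolls longer, so its OTDs shrink toward the
  standard. The inverse scaling (`"literal_ratio"`) and `"none"` are kept
  as options; the two non-trivial modes are exact inverses of each other.
* **Class bands**: the integer bands 0–33 / 34–66 / 67–100 are realised
  for continuous SI as half-open intervals with ties assigned downward
  (SI = 33 is RFS, SI = 66 is MFS), matching the windows being computed at
  exactly 33% and 66%. `classify_otd()` uses the same tie rule, which
  makes the two routes through one fitted model provably identical:
  classifying an OTD by its window equals classifying its predicted SI.

## Cutoff windows and their confidence bounds

Inverting the fitted line gives the point cutoffs
$\mathrm{OTD}^\ast = (\mathrm{SI}^\ast - c)/B$ at
$\mathrm{SI}^\ast \in \{33, 66\}$. Confidence bounds substitute the 95% CI
bounds of $B$ with the intercept held fixed:
$(\mathrm{SI}^\ast - c)/B_{\mathrm{lower}}$ and
$(\mathrm{SI}^\ast - c)/B_{\mathrm{upper}}$, reported in that slope-bound
order. This construction is deliberately chosen because it exactly
reproduces all sixteen published CI bounds of the reference calibration's
cutoff table from its regression table; a delta-method or Fieller interval
would also need the intercept's variance and the coefficient covariance,
which the published calibration does not report. The bounds should be read
as sensitivity of the cutoff to slope uncertainty, not as a full
confidence interval for the cutoff.

The reference calibration itself (four lines: pooled, level, +10°, −10°,
estimated on 25,655 analysed footfalls from 109 runners) ships in
`reference_lines()`, so classification works offline. One published
internal inconsistency is worth knowing: the pooled row's standardized
beta (0.859) and the pooled line's R² (0.836) cannot both hold in a
univariate fit, where beta² = R² identically; the subgroup rows are
self-consistent. The package therefore reports both quantities from its
own fits — where the identity is enforced by tests to 1e−9 — and
privileges neither published pooled value.

## What the synthetic-gait generator emulates

`simulate_footfalls()` draws the reference design: 109 subjects × 3
surfaces × 3 instructed patterns × 30 footfalls (29,430 records), one
foot length per subject (truncated normal, mean 24 cm, SD 1.5 cm, range
20–30 cm — a plausible adult range around the 23 cm normalisation
standard), and a split-belt flag per footfall, Bernoulli with rate
3775/29430 ≈ 0.1283 so the expected analysed count is exactly 25,655.

The statistical core per footfall on surface $s$ with instructed pattern
$p$:

1. a latent achieved-SI target $T \sim \mathcal{N}(\mu_p, \tau^2)$
   truncated to [0, 100], with $\mu_p = 25/50/75$ for RFS/MFS/FFS and
   $\tau = 5$;
2. the normalised OTD is the line point
   $\mathrm{OTD} = (T - c_s)/B_s$ (slopes/intercepts default to the
   reference calibration);
3. the recorded SI adds measurement scatter about the line,
   $\mathrm{SI} = T + B_s\,\eta$, $\eta \sim \mathcal{N}(0, \sigma_s^2)$,
   clamped to [0, 100];
4. the raw OTD inverts the foot-length normalisation.

Two design choices here were genuinely open and deserve their rationale:

* **The noise sits on the response.** Placing the scatter on OTD given SI
  instead (the "insole is the noisy instrument" reading) makes OLS of SI
  on OTD attenuate: the expected fitted slope becomes $B_s R^2$, about
  0.37 instead of 0.44, and no amount of data recovers the generating
  slope. Since the generator's stated purpose is to emulate data whose
  *fitted* agreement lines match the reference calibration, the scatter
  is placed on SI about the line (same magnitude, expressed in
  OTD-equivalent ms), making the OLS estimator unbiased for the
  generating slope.
* **Pattern centres 25/50/75 with SD 5 keep the linear model exact.**
  The per-surface R² targets (0.836/0.799/0.833) force a residual SD of
  about 9–11 SI points. Centres nearer the physical bounds (say 15/85)
  would put a sixth of RFS/FFS responses outside [0, 100]; clamping then
  bends the conditional mean at the extremes and biases the fitted slope
  by several standard errors at study size. With interior centres the
  clamp fraction is below ~1% and the bias is a fraction of one standard
  error. Real treadmill data *do* pile up near SI = 0 and 100 — the
  generator deliberately trades that realism for an exactly linear,
  recoverable model, which is what makes its round-trip and
  parameter-recovery guarantees meaningful.

The noise SDs are calibrated in closed form against the published
per-surface R²: with $V = \mathrm{Var}(T) \approx 441.7$ (the pattern
mixture variance),
$\sigma_s = \sqrt{V (1 - R^2_s) / R^2_s} / B_s$, giving 21.16 / 24.80 /
18.56 ms for flat / inclined / declined. These were fixed from the formula
and verified once by simulation at $n = 4 \times 10^5$.

`simulate_traces()` then renders any record as raw signals: a half-sine
vertical GRF (peak 1,500 N), a COP that starts at the SI position and
rolls monotonically toeward, a lateral COP inside or outside the split
zone per the record's flag, and FSR channels that jump to 0.2 and ramp to
saturation in 20 ms, with onsets separated by exactly the record's raw
OTD. All channels share one 1,000 Hz clock (configurable); an optional
uniform 0–3 ms per-channel lag emulates sensor response latency and is off
by default. What the traces do *not* emulate: impact transients, sensor
noise floors, COP mediolateral wander, belt-speed dynamics, or crosstalk —
so passing round-trip tests demonstrates correctness of the event-timing
chain, not robustness to every artefact of real hardware.

Quantisation bounds the round trip: onsets land on the sampling grid, so
recovered OTD is within one sample period (1 ms at 1,000 Hz), and the 10 N
contact crossing on a 1,500 N half-sine occurs ~0.5 ms after true contact,
during which the COP has rolled less than 0.2% of foot length — hence the
0.5-SI-point recovery bound.

## Verification choices and problem sizes

The test suite's statistical checks run at sizes chosen to keep the full
suite under a minute while leaving the checks sharp: noiseless fits at
n = 450 per surface (exact to 1e−9), slope/R² recovery at ~10,000
footfalls on one surface (2% tolerance), the OTD round-trip sweep over
−100…100 ms, and classification consistency on 10,000 random OTDs per
fitted model.

One acceptance-style check needs statistical care: "the fitted 95% CI
covers the generating slope in at least 95% of replicates" is, read
literally, a coin flip — a correctly specified interval covers at exactly
the nominal rate, so 200 replicates land at ≥190 successes only about
half the time. The suite therefore asserts empirical coverage within
three binomial standard errors of the nominal 0.95 (≥ 181/200 per
surface), which is the test a correct estimator passes with near
certainty and a biased one fails. Replicates use n ≈ 2,000 footfalls per
surface: large enough that the CI is tight (±0.004 on a slope of 0.44),
small enough that 600 replicate fits take seconds.

## Limitations

* The agreement lines are surface-specific; applying a window on the
  wrong inclination degrades classification materially (this is itself
  asserted in the tests). Field use would need an inclination estimate.
* Pooling footfalls ignores within-subject correlation; slope CIs are
  anti-conservative to that extent.
* The cutoff CI construction propagates slope uncertainty only.
* The generator's interior SI distributions understate boundary pile-up
  in real running data; agreement percentages computed on synthetic data
  are illustrative, not field estimates.
* Running speed is not a covariate anywhere in the model.
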