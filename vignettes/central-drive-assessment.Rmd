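---
title: "Burst-superimposition assessment of plantarflexor central drive: methods and design"
author: "burstdrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst-superimposition assessment of plantarflexor central drive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstdrive)
```

## The measurement problem

Central drive is the fraction of a muscle's force-generating capacity that a
person can access volitionally. It is measured with the burst-superimposition
(interpolated twitch) technique: while the participant holds an isometric
plantarflexion contraction, a brief supramaximal electrical burst (150 ms,
100 Hz, 150 mA; 15 biphasic pulses) is delivered to the calf muscles. Torque
rises above the voluntary level by however much capacity volition left
unaccessed. Two forces are read off the torque trace:

* `F_vol` - the mean torque over the 100 ms before the burst (the voluntary
  plateau), and
* `F_stim` - the peak torque after burst onset.

The *device-measured* central drive is `F_vol / F_stim`. The *true* central
drive is `F_vol / MFGA`, where MFGA (maximum force-generating ability) is the
peak torque reached when the burst is superimposed on a maximal contraction.
Because an electrically evoked contraction does not recruit everything that
volition missed, `F_stim` underestimates MFGA and the measured ratio
overestimates true central drive. The package's central object is the
**adjustment equation** - an origin-constrained cubic

\[
\widehat{\mathrm{CD}}_{\mathrm{true}} = b_3 x^3 + b_2 x^2 + b_1 x,
\qquad x = \mathrm{CD}_{\mathrm{measured}},
\]

calibrated on a cohort in which both quantities are observable, then applied
to cohorts (clinical populations) in which MFGA cannot be trusted. The
intercept is fixed at zero because a measured central drive of zero must map
to a true central drive of zero. The package ships a reference calibration
for the portable CEDRS device,

```{r}
reference_adjustment_model()
```

which is strictly increasing on [0, 1] and reaches 0.894 at `x = 1`: adjusted
values cannot exceed 89% even at a measured central drive of 100%, a known
ceiling of this calibration form.

## Signal processing and trial quality control

Traces are sampled at 1 kHz with a binary trigger channel carrying the single
contiguous burst. Torque is low-pass filtered at 10 Hz with an effective
fourth-order Butterworth response. The default implementation applies a
second-order design forward and backward (`lowpass_filter(zero_phase = TRUE)`),
which squares the magnitude response and cancels the phase: burst-relative
windows are not shifted in time. A single-pass causal fourth-order option is
available for sensitivity analyses.

Two numerical choices matter here:

* **Edge handling.** Each pass is initialised at the steady state of its
  first sample and the trace is extended by short odd-reflection padding
  (three filter lengths). A constant trace passes through exactly; boundary
  transients stay local to the trace ends, far from the analysis windows.
* **Pre-burst isolation.** A zero-phase filter is non-causal, so the large
  stimulation response would smear *backwards* into the 100-ms voluntary
  window if the whole trace were filtered in one piece - inflating `F_vol`,
  its variance, and its slope. `summarize_trial()` therefore filters the
  voluntary segment (everything before burst onset) in isolation for
  `F_vol` and the quality-control statistics, and uses the fully filtered
  trace only for the post-burst peak `F_stim`.

Trial validity automates what is otherwise a visual steadiness judgement
(`qc_config()` defaults, all configurable):

| rule | statistic | default threshold |
|---|---|---|
| `high_variance` | sample variance of the 100-ms window | > 0.1 (ft-lbs)^2 |
| `nonsteady` | absolute OLS slope of the window | > 2.0 ft-lbs/s |
| `submax_90` | `F_vol` vs within-trial pre-burst peak | < 90% of peak |
| MVC acceptance | `F_vol` vs MFGA | >= 95%, up to 3 attempts |

The variance threshold is stated in the source protocol without units or
window; we interpret it as (ft-lbs)^2 over the `F_vol` window and expose it in
configuration. The 2.0 ft-lbs/s slope default is a deterministic surrogate
for the qualitative "increasing or decreasing" criterion; it is conservative
relative to plateau noise at 10-Hz bandwidth (filtered noise at the study's
levels produces slopes well under 1 ft-lbs/s). Boundary conventions are
fixed: variance and slope flags are strict inequalities (a trial exactly at
threshold passes; a 1e-9 epsilon keeps this deterministic under floating
point), the submaximal flag is strict, MVC acceptance is inclusive. The
submaximal rule was introduced for post-stroke testing, where a participant
may peak and drop off before the burst arrives; here it excludes the trial
(configurable), whereas the original protocol used it to trigger visual
inspection. All sample indices are 1-based (R convention) with half-open
windows; the burst onset is the first sample of the trigger run.

`F_vol` and `F_stim` are averaged over the *valid* trials of a
participant-limb; a limb with zero valid trials is a reportable state that is
excluded from group statistics, not an error.

## Calibration diagnostics

`fit_adjustment()` is ordinary least squares on the basis `{x, x^2, x^3}`
with no intercept, and reports:

* 95% coefficient confidence intervals from the linear-model covariance;
* R-squared against the mean of the response. For no-intercept models the
  centered and uncentered conventions differ, and published values rarely
  say which was used, so both are reported (`r_squared`,
  `r_squared_uncentered`);
* RMSE in percentage points of central drive;
* leave-one-participant-out cross-validation (`loocv_adjustment()`): refit
  without each participant, score on their held-out pairs, report the mean
  and SD of per-participant RMSEs. With seven pairs per participant the
  relative SD of a fold RMSE is about `1/sqrt(14)` (~27%) even under
  perfectly homogeneous noise - a useful baseline when reading the SD as a
  stability diagnostic;
* the Breusch-Pagan test in its Lagrange-multiplier form: squared residuals
  regressed on the measured central drive, statistic `n R^2` against
  chi-square(1). The protocol names the test but not the variant or
  regressor; this is the standard studentized form.

Measured ratios above 1 (possible under noise when no augmentation is
recorded) are capped at 1 and flagged, keeping the adjustment domain [0, 1].

## Agreement and cohort statistics

Device agreement uses ICC(2,1) - two-way random effects, absolute agreement,
single measurement - computed from the two-way ANOVA decomposition, with the
F-based confidence interval for that form, plus Bland-Altman limits of
agreement (`bias +/- 1.96 SD` of paired differences, n-1 denominator).
Group comparisons are one-way ANOVAs with eta-squared effect sizes
(noncentral-F inversion for the interval, converted through
`eta^2 = lambda/(lambda + N)`) and Sidak-adjusted pooled-variance pairwise t
tests (`p_adj = 1 - (1 - p)^m` over the `m` pairs). Walking function uses
the six-minute walk test: total distance and the percent change in distance
between the first and sixth minutes, with positive values meaning the
participant sped up (the sign is declared in output metadata because
published reports often state only counts of who sped up or slowed down).

One statistical caveat is replicated deliberately: the between-limb ANOVA
treats the paretic and non-paretic limbs of the same participants as
independent groups, as the validation design it mirrors did.

## The simulator

No torque-trace data accompany the protocol this package operationalises, so
the synthetic-data module is a first-class component: it generates traces,
participants and cohorts with known ground truth for every downstream stage.
The forward model is deliberately minimal:

* voluntary torque rises along a raised-cosine ramp and reaches the plateau
  `F_vol = effort x true_cd_max x MFGA` *exactly* at `4 tau_rise`
  (default 2 s). A saturating ramp (rather than an asymptotic exponential)
  is used so that noise-free extraction recovers generator values exactly -
  the basis of the pipeline's exactness tests;
* the burst drives torque first-order (time constant 40 ms) toward
  `F_vol + k (MFGA - F_vol)` for 150 ms, then decays (150 ms constant). A
  150-ms burst closes `1 - exp(-150/40)` = 97.6% of the gap, so the
  attainable noiseless peak sits just below the asymptotic target; the
  ground-truth record carries both values;
* the single parameter `k` (stimulator efficacy, per participant, default
  Uniform(0.6, 0.9)) produces the overestimation the adjustment equation
  exists to correct: measured central drive relates to true central drive by
  `true = k m / (1 - (1 - k) m)`, so a mixture of `k` values across a cohort
  yields the nonlinear measured-true relationship that motivates the cubic;
* devices differ by an affine gain/offset (calibration-experiment default:
  offset drawn per participant from N(3.7, 6.64^2) ft-lbs);
* twitch recruitment is saturating-linear in pulse width with a plateau at
  the participant's saturation width (350-600 us), peak 12% of MFGA;
* clinical cohorts draw per-limb MFGA and *adjusted* central drive from the
  group distributions (defaults: neurotypical 76.47 +/- 13.59 ft-lbs and
  88.7 +/- 1.7%; paretic 41.07 +/- 13.41 and 50.4 +/- 21.4%; non-paretic
  56.54 +/- 15.71 and 70.1 +/- 20.2%; n = 16/26/26 limbs, three MVC trials
  per clinical limb, one per neurotypical limb). The target adjusted value
  is inverted through the adjustment model and the constant-k map to a
  volitional ceiling, so the pipeline's output lands on the configured
  distribution;
* six-minute-walk-test minute distances follow a linear drift whose total
  and first-to-sixth-minute change are constructed to correlate with paretic
  adjusted central drive at a configurable `r_target` (default 0.65). A
  direct correlation-targeting construction was chosen over a nonlinear
  (e.g. logistic) link precisely so the target correlation is controllable;

All randomness flows from one explicit seed through a deterministic
per-participant/per-trial splitter, so cohorts are bitwise reproducible.

What the simulator does **not** emulate: antagonist co-contraction, fatigue,
electrode-placement physics, age effects, or any empirical torque-trace
shape beyond the plateau-plus-burst structure. Passing tests therefore
demonstrate that the pipeline recovers the quantities this model encodes at
realistic noise levels - not that the model reproduces every feature of
human dynamometry data.

### Power of the group-comparison replication

With group means and SDs at their defaults, the weakest pairwise contrast
(paretic vs non-paretic central drive, Cohen's d of about 0.95 at n = 26 per
limb) has roughly 80% power at the Sidak-adjusted alpha of 0.017. A freshly
simulated cohort therefore reproduces *all* pairwise differences at p < 0.05
in only about three quarters of seeds, even though the group *ordering*
reproduces essentially always. This is a property of the underlying effect
sizes, not of the pipeline; the test suite asserts both layers separately so
the distinction stays visible.

## Problem sizes and determinism

The shipped tests run the simulator at the study's scale (16-participant
calibration cohorts, 68-limb clinical cohorts, 112 calibration pairs) and
use replicated small simulations (100-1000 replicates) for coverage, size
and power properties; fixed seeds make every number reproducible. Where a
recovered quantity has non-negligible sampling variance - the cubic
coefficient of the origin-constrained fit has SD ~0.11 across 112-pair
replicates because `{x, x^2, x^3}` is near-collinear on (0.1, 1) - point
recovery is asserted on Monte Carlo means over replicated fits, and
interval coverage is asserted per fit.

## Known limitations

* The adjustment ceiling (89% at measured 100%) means the pipeline cannot
  distinguish true central drive in the 89-100% range for high-performing
  participants; an alternative adjustment form would be needed there.
* The reference calibration is device-specific; applying it to data from a
  different device family is not supported by its derivation.
* The variance threshold's units/window interpretation and the
  submaximal-rule disposition are declared, configurable choices, not
  facts about the original protocol.
* QC verdicts approximate a visual adjudication process with fixed
  thresholds; borderline trials a human would keep (or drop) can be
  classified differently.
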