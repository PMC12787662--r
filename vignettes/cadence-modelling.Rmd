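---
title: "Detecting and modelling movement cadence from a single trunk-worn IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling movement cadence from a single trunk-worn IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tricadence)
```

`tricadence` measures movement cadence — propulsive events per minute —
from a single trunk-mounted inertial measurement unit worn during
triathlon races, and models how cadence changes across a competitive
season. This vignette is the package's own account of the methods: the
detection algorithm and its tunable parameters, the longitudinal models
and their estimation, the synthetic-data generators that stand in for
device recordings, and the numerical and design choices made along the
way.

## 1. Event detection

A trunk-worn IMU samples tri-axial acceleration (m/s²) and angular
velocity (deg/s) at 100 Hz. Each discipline expresses its propulsive
rhythm on a different axis:

* **swimming** — trunk roll makes the *medio-lateral* accelerometer
  oscillate once per stroke pair; each peak and each trough is counted
  as one stroke;
* **cycling** — pedalling rocks the pelvis about the vertical axis, so
  peaks and troughs of the *yaw* gyroscope are pedal-stroke candidates,
  each confirmed only if the *antero-posterior* accelerometer shows an
  extremum within ±0.15 s (uncorrelated noise extrema fail this
  cross-sensor check);
* **running** — each stride lands one impact on the *vertical*
  accelerometer; peaks only are counted.

The processing chain per channel is: a 3-point running-median prefilter
(removes single-sample artifact spikes), a zero-phase 4th-order
Butterworth low-pass (`signal::butter` applied forward and backward with
odd-reflection edge padding, so the effective gain is the squared
one-pass response and start-up transients stay out of the record), local
extremum detection with a topographic-prominence threshold, and greedy
refractory thinning.

Tunable parameters, with defaults:

| parameter | swim | cycle | run | why |
|---|---|---|---|---|
| low-pass cutoff (Hz) | 3 | 6 | 8 | passes the fundamental event frequency (≤ 0.7, 1.7, 1.6 Hz) with margin; rejects broadband noise and impact ringing |
| refractory interval (s) | 0.5 | 0.25 | 0.5 | below the inter-event interval at each discipline's maximum plausible cadence (80, 200, 95 events/min); the admissible range is 0.25–0.5 s |
| prominence fraction | 0.2 | 0.2 | 0.2 | scale-free rejection of noise extrema |
| confirmation window (s) | — | 0.15 | — | half the cycling refractory interval |
| absolute floor (units) | 0.5 | 0.5 | 0.5 | silences channels carrying only low-level noise |

Two definitions deserve a note. The *robust amplitude* against which
prominence is judged is the 1%–99% inter-quantile range of the filtered
channel, not a MAD: for a sustained oscillation the two agree, but for a
running impact train (signal near baseline most of the time) the MAD
tracks the noise floor and would let noise bumps through, whereas the
high-quantile range tracks the impacts. Second, a purely relative
threshold cannot distinguish "small genuine signal" from "pure noise",
so an absolute prominence floor (0.5 m/s² or deg/s) is applied; channels
whose content stays below it yield zero events. Prominence itself is
topographic (height above the higher of the two saddles towards higher
ground), except that a side whose scan reaches the record boundary
without meeting higher ground does not cap the prominence — the
recording merely truncates the view there, and without this rule extrema
near the record edges would be lost and detection would not be
equivariant under time shifts.

In refractory thinning, candidates are processed in order of decreasing
prominence (ties towards the earlier sample) and a candidate is kept
only if no kept event lies within the refractory interval — so of two
identical spikes 0.2 s apart, exactly one survives at a 0.25 s interval.
Cycling confirms candidates first and thins afterwards.

## 2. Race processing

Race observations carry exclusion flags (`unwell`,
`injured_during_race`, `imu_attachment_fault`, `gps_fail`). Processing
runs in a fixed order: same-day races by the same athlete in the same
discipline are first averaged to a single result (the races, not the
samples, are the unit of exclusion; flags are pooled), then flagged
observations are removed, then the chaining rule is applied: because
each leg's performance depends on the preceding leg, a cycle observation
survives only if the same-day swim did, a run only if both swim and
cycle did. A missing race distance (GPS failure) is imputed as the mean
distance recorded by the other participants' working sensors in the same
race; velocity is distance over duration and is carried descriptively
but never modelled. Week numbers count from the first race week of the
season calendar by default; a per-participant convention ("each athlete's
own first week") is available as a switch, since sparse individual
racing schedules make the two genuinely different.

## 3. The season models

Let `C_it` be athlete *i*'s average cadence in week `W_it`. Both models
include a season offset (season 1 is the reference) and per-athlete
random intercepts and random slopes of week:

* linear: `C_it = β0 + β1 W_it + β2 season_it + b0i + b1i W_it + ε_it`
* non-linear: `C_it = β0 + f(W_it) + β2 season_it + b0i + b1i W_it + ε_it`

with `b0i ~ N(0, σ_b0²)`, `b1i ~ N(0, σ_b1²)`, `ε_it ~ N(0, σ²)`. `f`
is a rank-reduced thin-plate regression spline of dimension `k = 10`
(the standard default for this basis; configurable, and capped at the
number of distinct weeks): the radial basis `|r|³/12` on the unique week
values is eigen-truncated to the leading directions, the linear
side-conditions are absorbed, and all columns are centred to sum to zero
over the observed weeks so the smooth is identifiable against the
intercept. Straight lines are unpenalized by the spline penalty.

Everything is fitted as one penalized least-squares problem; random
effects are ridge-penalized indicator blocks (random-effect smooths), so
individual trajectories are pooled towards the population mean exactly
as the variance components dictate. Smoothing and precision parameters
minimize the exact Gaussian restricted-likelihood criterion over their
logarithms (Nelder–Mead from three fixed starts, relative tolerance
1e-10; a soft barrier keeps log-parameters within ±25). The smooth
carries a *double penalty*: its null-space (linear) component gets its
own shrinkage parameter, so the smooth's effective degrees of freedom —
the trace of its block of the influence matrix — can fall below one and
even to zero when athletes share no common trend. This matters in
practice: a near-zero smooth eDF is exactly how "no common change over
the season" (the cycling-like case) manifests, and a basis whose linear
part cannot shrink would never show it. `σ̂²` is the restricted-likelihood
estimate; `σ̂_b0², σ̂_b1²` follow from the fitted precisions.

Reported per fit: coefficients with standard errors from the Bayesian
coefficient covariance `σ̂² (X'X + S_λ)⁻¹`; conditional log-likelihood at
the fitted values; `AIC = −2ℓ + 2·eDF_total` and
`BIC = −2ℓ + log(n)·eDF_total` (effective-df flavour — naive parameter
counts are meaningless for penalized fits);
`r²_adj = 1 − (RSS/(n−eDF_total))/(TSS/(n−1))`, deliberately not clipped
at zero.

### Model comparison

`compare_models` reports AIC/BIC/r² for both fits and a likelihood-ratio
statistic `D` referred to a chi-squared with
`df = max(eDF_nl − eDF_lin, 0.5)`. The likelihoods entering `D` are
*marginal maximum likelihoods*: the penalized blocks are integrated out
(exact Gaussian form) and each model's smoothing/precision parameters
are re-optimized under the ML criterion. Two facts, both verified by
simulation in this package's test suite, force this choice:

* a `D` built from the conditional likelihoods of the penalized fits is
  strongly anti-conservative (measured type-I error 0.13–0.31 at
  α = 0.05 under a linear-truth null, depending on the df flavour),
  because the flexibility spent selecting λ is not counted — the same
  comparison done with a popular GAM toolkit's `anova` rejected 72% of
  nulls under identical conditions;
* the marginal-ML ratio is the standard test for nested Gaussian mixed
  models and shows no type-I inflation (measured 0.000 with power 1.0
  against a u-shaped trend of five residual SDs).

The null hypothesis pins variance parameters to the boundary of their
space, so the chi-squared reference is approximate and *conservative*:
under linear truth the statistic is exactly zero in ~95% of replicates,
and p-values near the boundary should be read qualitatively. The result
carries a `boundary_approx` flag. A parametric bootstrap would calibrate
the test exactly at roughly a hundredfold compute cost; it is not
implemented.

### Prediction, intervals, percentage change

Group-level curves set the random effects to zero;
`CI = fit ± 1.96 × SE` pointwise (not simultaneous) from the covariance
of the fixed-plus-smooth coefficients. Across-the-function coverage of
such intervals is close to nominal — measured 0.93 over 200 u-shape
simulations. Individual-level curves add each athlete's `b0i + b1i·W`.
Evaluating outside the observed week range warns and flags the result
rather than failing. On a one-week grid the per-week percentage change
is `100·(mean[w+1] − mean[w])/mean[w]`, and a window summary is its
arithmetic mean over the window's transitions.

Normality of each discipline's cadence sample is checked with a
one-sample Kolmogorov–Smirnov statistic against a normal with
sample-estimated mean and SD; because the parameters are estimated, the
p-value comes from seeded Monte-Carlo recalibration (Lilliefors-style,
2000 replicates by default) rather than the naive KS distribution.

## 4. Synthetic data

The signal generator emulates what the detectors must survive, not
swimming/cycling/running biomechanics. The base waveform is sinusoidal
with per-cycle period jitter (lognormal multiplicative factors of mean 1
and the configured CV, drawn as one stream before any other RNG use);
running impacts are Gaussian pulses of 60 ms full width at half maximum.
Event rates are specified uniformly as ground-truth events/min —
plausible ranges are 50–80 (swim), 150–200 (cycle), 75–95 (run). The
first event sits half an interval after the start and a matching
half-interval margin is kept at the end, since an extremum completing
within the final fraction of a cycle is not physically observable.
Amplitudes default to 3 m/s² (swim), 30 deg/s with a 1.5 m/s²
phase-locked companion (cycle) and 8 m/s² (run). Degradations: additive
white Gaussian noise calibrated in dB SNR against the clean channel RMS,
a 0.1 Hz baseline wander of 0.5 units by default, and 1-sample artifact
spikes of five signal amplitudes at a configured rate; off-axis channels
carry pure noise so axis selection is testable. None of this reproduces
real stroke asymmetries, turns, coasting or gear changes — passing the
detection suite shows robustness to noise, jitter, drift and spikes, not
device-grade validity on real athletes.

The season generator inverts the non-linear model: it draws `b0i`,
`b1i`, `ε_it` at configured SDs (defaults 4, 0.2 and 2 events/min — of
the order of between-athlete spread, slow individual drift and race-to-
race variation plausible for junior athletes) around a selectable
population trend: `flat`, `linear`, a `u_shape` Gaussian dip centred
mid-season (the swim-like pattern: cadence drops, then recovers), or a
saturating `rise_plateau` logistic (the run-like pattern). Defaults are
12 athletes racing every third week of a 27-week season; with two
seasons, a third of athletes race both and weeks restart each season
(season enters as a fixed offset — the week covariate is season-reset,
matching how the model equations treat a season as its own calendar).
The generator returns the full truth record (coefficients, random
effects, trend values, residuals), so observations are exactly
reconstructible and fitted models can be scored against truth.

## 5. Numerical choices and edge cases

* Problem sizes in the test suite are chosen to finish a full run in
  minutes while keeping Monte-Carlo error well inside the asserted
  bands: 60 five-minute recordings per discipline for detection
  accuracy, 30 seeds of 40 athletes × 15 weeks for variance-component
  recovery, 200 replicates for test size and coverage, 100 for power.
* The spline penalty is scaled to unit mean diagonal (a pure
  reparametrization of λ) and its eigenvalues clipped at zero, keeping
  the restricted-likelihood log-determinants well conditioned.
* Cholesky solves throughout; a failed factorization retries once with a
  1e-8 ridge and then raises a rank-deficiency error.
* Degenerate inputs raise classed errors (`invalid_config`,
  `missing_channel`, `degenerate_input`, `insufficient_support`,
  `incomparable_fits`, ...) rather than producing numbers.
* `k` larger than the number of distinct weeks is capped silently; fewer
  than three distinct weeks is an error.
* Refractory ties (equal prominence) resolve to the earlier event, so
  detection is deterministic.
* All generators accept a seed and scope it locally (the ambient RNG
  stream of the session is never disturbed); the pipeline fans one
  master seed out into per-stage, per-recording child seeds, making
  `report.json` byte-identical across runs.

## 6. Known limitations

* The detectors assume a fixed, correct sensor orientation; real-world
  attachment faults are handled by exclusion flags, not by re-alignment.
* Swim stroke counting reads "peaks and troughs" as two events per full
  oscillation; if a deployment defines a stroke as one full cycle,
  halve the rates.
* The duathlon special case (run–cycle–run) is out of scope; such races
  must be pre-labelled and only their final segment supplied.
* LRT p-values are conservative near the variance boundary (see §3);
  AIC/BIC comparisons do not suffer from this and are reported
  alongside.
* Cadence in cycling confounds with gearing and coasting; the package
  measures cadence, it cannot de-confound it.
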