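# tricadence

Movement cadence — swimming strokes, cycling pedal strokes and running
strides per minute — is a core motor-skill parameter in triathlon: an
athlete who re-parameterises the speed of a stored movement pattern
changes the cadence, so tracking cadence across a season of races tracks
motor-skill development. `tricadence` implements the full analysis chain
for doing this with a single trunk-worn inertial measurement unit (IMU):

1. **Event detection** from 100 Hz accelerometer/gyroscope traces: a
   zero-phase Butterworth low-pass, prominence-thresholded peak/trough
   detection with a 0.25–0.5 s refractory ("minimum detection") interval,
   discipline-specific axis selection (medio-lateral acceleration for
   swimming, yaw angular velocity cross-confirmed against
   antero-posterior acceleration for cycling, vertical acceleration peaks
   for running), and `cadence = 60 * count / duration`.
2. **Race processing**: same-day race averaging, flag-based exclusions
   with the preceding-leg chaining rule (a cycle leg is analysable only if
   the swim was, a run only if swim and cycle were), GPS-distance
   imputation from peers in the same race, race velocity, week numbering.
3. **Longitudinal models** of average cadence `C` on week number `W`,
   fitted by restricted maximum likelihood with per-athlete random
   intercepts and slopes:

   - linear: `C_it = b0 + b1 W_it + b2 season_it + b0i + b1i W_it + e_it`
   - non-linear: `C_it = b0 + f(W_it) + b2 season_it + b0i + b1i W_it + e_it`

   where `f` is a rank-reduced thin-plate regression spline under a
   double penalty (its effective degrees of freedom can shrink to zero),
   `b0i ~ N(0, s_b0^2)`, `b1i ~ N(0, s_b1^2)`, `e_it ~ N(0, s^2)`.
   The two models are compared by AIC, BIC, adjusted r², and a marginal
   maximum-likelihood ratio test; prediction curves carry pointwise 95%
   confidence intervals and weekly percentage-change summaries.
4. **Synthetic data**: generators for IMU recordings with exactly known
   ground-truth event times and for season-long cadence datasets with
   known model parameters, so the whole chain is testable without any
   device data.

The penalized REML/ML machinery (spline basis and penalty, restricted and
marginal likelihood criteria, effective degrees of freedom, Bayesian
coefficient covariance) is implemented in the package itself; `mgcv` is
used only as an independent cross-check in the test suite.

## Worked example

```r
library(tricadence)

# simulate one noisy 5-minute swim at 64 strokes/min and detect the strokes
sim <- gen_imu_recording(signal_gen_config(
  "swim", duration_s = 300, cadence = 64, jitter_cv = 0.05,
  noise_snr_db = 10, spike_rate_per_min = 2, seed = 42))
det <- detect_swim_strokes(sim$recording)
c(truth = sim$truth$count, detected = det$count,
  cadence = average_cadence(det, 300))
#>    truth detected  cadence
#>      320      320       64

# a season of races with a mid-season dip in cadence, and both models
season <- gen_season_dataset(season_gen_config(
  trend_shape = "u_shape", trend_amp = 4, seed = 42))
fit_lin <- fit_model(season$data, design_spec("linear"))
fit_nl  <- fit_model(season$data, design_spec("nonlinear"))
fit_nl
#> <cadence_gam> nonlinear model, n = 120, 12 athletes
#>   beta0 = 60.189 (SE 1.529)
#>   sigma_b0 = 4.094, sigma_b1 = 0.2720, sigma = 1.915
#>   eDF(smooth) = 4.16, eDF(total) = 25.95, AIC = 519.20, BIC = 591.54, adj r2 = 0.906
compare_models(fit_lin, fit_nl)
#> <model comparison> linear vs non-linear
#>   AIC  582.55 vs 519.20
#>   BIC  642.95 vs 591.54
#>   r2   0.836 vs 0.906
#>   D = 40.911 on 4.28 df, p = 4.052e-08  (boundary chi-squared approximation)

curve <- predict_curve(fit_nl, 0:27)
weekly_percent_change(curve, window = c(18, 27))$window_mean
#> [1] 0.3874959
```

The smooth's estimated degrees of freedom (~4) flag genuine curvature —
the mid-season dip — and the likelihood-ratio test rejects the linear
model; on flat- or linear-truth seasons the same smooth collapses to
eDF ≈ 0–1 and the test does not reject. The percentage change summarises
how fast the predicted population cadence rises late in the season.

The full pipeline (simulate → detect → assemble → model → report):

```r
report <- run_end_to_end(pipeline_config(seed = 1, out_dir = "out"))
```

writes `season.csv`, per-recording `events/*.csv`, per-discipline
prediction curves, a `pipeline.log`, and a `report.json` holding every
fit, comparison and detection-accuracy figure; outputs are byte-identical
under the same seed.

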