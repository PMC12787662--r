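# Shared fixtures, all generated in code.

clean_recording <- function(discipline, duration_s = 60, cadence = NULL,
                            seed = 1, ...) {
  gen_imu_recording(signal_gen_config(
    discipline, duration_s, cadence = cadence, jitter_cv = 0,
    noise_snr_db = Inf, drift_amp = 0, spike_rate_per_min = 0,
    seed = seed, ...))
}

noisy_recording <- function(discipline, duration_s = 120, cadence = NULL,
                            seed = 1, noise_snr_db = 10, jitter_cv = 0.05,
                            spike_rate_per_min = 2, ...) {
  gen_imu_recording(signal_gen_config(
    discipline, duration_s, cadence = cadence, jitter_cv = jitter_cv,
    noise_snr_db = noise_snr_db, spike_rate_per_min = spike_rate_per_min,
    seed = seed, ...))
}

count_accuracy <- function(detected, truth) {
  100 * (1 - abs(detected$count - truth$count) / truth$count)
}

# Six observations, one participant each: the degenerate fixture on which
# the mixed machinery must collapse to ordinary least squares.
ols_fixture <- function() {
  data.frame(cadence = c(60.2, 61.1, 59.8, 62.3, 63.0, 61.7),
             week = c(0, 2, 4, 6, 8, 10),
             participant_id = paste0("P", 1:6))
}

season_fixture <- function(seed = 42, shape = "u_shape", ...) {
  gen_season_dataset(season_gen_config(
    n_participants = 12, weeks = seq(0, 27, by = 3), trend_shape = shape,
    beta0 = 60, trend_amp = 4, sd_b0 = 4, sd_b1 = 0.2, sd_eps = 2,
    seed = seed, ...))
}

# Race-observation table builder for the processing rules.
race_obs <- function(participant, date, discipline, cadence = 80,
                     distance = 5000, duration = 1500, flags = "",
                     season = 1) {
  data.frame(participant_id = participant, date = date, season = season,
             discipline = discipline, cadence = cadence,
             distance_m = distance, duration_s = duration, flags = flags,
             stringsAsFactors = FALSE)
}
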