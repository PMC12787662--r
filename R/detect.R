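#' Detection parameters
#'
#' Tunable parameters of the peak-counting cadence detector. The refractory
#' (minimum detection) interval must lie within 0.25-0.5 s; together with
#' the prominence rule it prevents artifact peaks and troughs from being
#' counted as events.
#'
#' @param cutoff_hz Low-pass corner frequency (Hz).
#' @param min_interval_s Refractory interval (s), within \[0.25, 0.5\].
#' @param filter_order Butterworth order (even, default 4).
#' @param prominence_frac Minimum extremum prominence as a fraction of the
#'   filtered channel's robust (1%-99% inter-quantile) amplitude.
#' @param confirm_window_s Cycling-only cross-check window (s): a yaw
#'   candidate counts only if an antero-posterior accelerometer extremum
#'   lies within this distance.
#' @param noise_floor Absolute prominence floor in channel units; channels
#'   whose content stays below it yield no events.
#' @param despike Apply a 3-point running-median prefilter that removes
#'   1-sample artifact spikes before low-pass filtering (default TRUE).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(cutoff_hz, min_interval_s,
                             filter_order = 4,
                             prominence_frac = 0.2,
                             confirm_window_s = 0.15,
                             noise_floor = 0.5,
                             despike = TRUE) {
  check_scalar(cutoff_hz, "cutoff_hz", lower = 0, strict_lower = TRUE,
               class = "invalid_parameter")
  if (!is_scalar_num(min_interval_s) ||
      min_interval_s < 0.25 || min_interval_s > 0.5) {
    tri_abort("min_interval_s must lie within [0.25, 0.5] s",
              "invalid_parameter")
  }
  if (!is_scalar_num(filter_order) || filter_order < 2 ||
      filter_order %% 2 != 0) {
    tri_abort("filter_order must be an even integer >= 2", "invalid_parameter")
  }
  check_scalar(prominence_frac, "prominence_frac", lower = 0,
               class = "invalid_parameter")
  check_scalar(confirm_window_s, "confirm_window_s", lower = 0,
               class = "invalid_parameter")
  check_scalar(noise_floor, "noise_floor", lower = 0,
               class = "invalid_parameter")
  structure(list(cutoff_hz = cutoff_hz, min_interval_s = min_interval_s,
                 filter_order = filter_order,
                 prominence_frac = prominence_frac,
                 confirm_window_s = confirm_window_s,
                 noise_floor = noise_floor, despike = isTRUE(despike)),
            class = "detection_params")
}

#' Default detection parameters per discipline
#'
#' Defaults pass each discipline's fundamental event frequency with margin
#' while rejecting noise and impact ringing: cutoffs swim 3 Hz / cycle 6 Hz
#' / run 8 Hz; refractory intervals swim 0.5 s, cycle 0.25 s, run 0.5 s
#' (below the inter-event interval at each discipline's maximum plausible
#' cadence).
#'
#' @param discipline `"swim"`, `"cycle"` or `"run"`.
#' @return A [detection_params()] object.
#' @export
default_detection_params <- function(discipline) {
  discipline <- match.arg(discipline, c("swim", "cycle", "run"))
  switch(discipline,
         swim = detection_params(cutoff_hz = 3, min_interval_s = 0.5),
         cycle = detection_params(cutoff_hz = 6, min_interval_s = 0.25),
         run = detection_params(cutoff_hz = 8, min_interval_s = 0.5))
}

#' Read / write per-discipline detection parameters as YAML
#'
#' The file maps each discipline name to a block of [detection_params()]
#' fields; missing fields fall back to the discipline defaults.
#'
#' @param path File path.
#' @param params Named list of [detection_params()] keyed by discipline.
#' @return `read_detection_config` returns a named list of
#'   [detection_params()]; `write_detection_config` returns `path`
#'   invisibly.
#' @export
read_detection_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  for (disc in names(raw)) {
    base <- unclass(default_detection_params(disc))
    base$despike <- NULL
    spec <- raw[[disc]]
    for (f in names(spec)) base[[f]] <- spec[[f]]
    out[[disc]] <- do.call(detection_params, base)
  }
  out
}

#' @rdname read_detection_config
#' @export
write_detection_config <- function(params, path) {
  yaml::write_yaml(lapply(params, unclass), path)
  invisible(path)
}

prepare_channel <- function(x, fs, params) {
  if (params$despike && length(x) >= 3L) x <- stats::runmed(x, 3)
  butterworth_lowpass(x, fs, params$cutoff_hz, params$filter_order)
}

detect_on_channel <- function(rec, channel, params, mode) {
  x <- rec_channel(rec, channel)
  fs <- sample_rate(rec)
  if (length(x) <= 3 * params$filter_order) {
    tri_abort("recording too short for detection", "degenerate_input")
  }
  xf <- prepare_channel(x, fs, params)
  idx <- find_extrema(xf, fs, params$min_interval_s,
                      prominence_frac = params$prominence_frac,
                      mode = mode, noise_floor = params$noise_floor)
  list(idx = as.integer(idx), filtered = xf, times = rec$time_s[idx])
}

#' Detect swimming strokes
#'
#' Counts peaks and troughs of the low-pass-filtered medio-lateral
#' accelerometer channel; each retained extremum is one stroke.
#'
#' @param rec An [imu_recording()].
#' @param params A [detection_params()]; defaults to
#'   `default_detection_params("swim")`.
#' @return An [event_series()].
#' @export
detect_swim_strokes <- function(rec, params = default_detection_params("swim")) {
  det <- detect_on_channel(rec, "acc_ml", params, "peaks_and_troughs")
  event_series(det$times, "swim", params$min_interval_s)
}

#' Detect cycling pedal strokes
#'
#' Candidate events are the peaks and troughs of the filtered yaw-gyroscope
#' channel; a candidate is confirmed only if an extremum of the filtered
#' antero-posterior accelerometer lies within `confirm_window_s` of it.
#' Confirmed events are refractory-thinned.
#'
#' @inheritParams detect_swim_strokes
#' @return An [event_series()].
#' @export
detect_cycle_pedal_strokes <- function(rec,
                                       params = default_detection_params("cycle")) {
  ap <- rec_channel(rec, "acc_ap")  # fail fast on missing confirmation channel
  yaw <- rec_channel(rec, "gyr_yaw")
  fs <- sample_rate(rec)
  if (length(yaw) <= 3 * params$filter_order) {
    tri_abort("recording too short for detection", "degenerate_input")
  }
  # candidates: prominent yaw extrema, not yet refractory-thinned
  yawf <- prepare_channel(yaw, fs, params)
  cand <- find_extrema(yawf, fs, min_interval_s = 0,
                       prominence_frac = params$prominence_frac,
                       mode = "peaks_and_troughs",
                       noise_floor = params$noise_floor)
  if (length(cand) == 0L) {
    return(event_series(numeric(0), "cycle", params$min_interval_s))
  }
  apf <- prepare_channel(ap, fs, params)
  # confirmation extrema: prominence-thresholded, no refractory thinning
  ap_idx <- find_extrema(apf, fs, min_interval_s = 0,
                         prominence_frac = params$prominence_frac,
                         mode = "peaks_and_troughs",
                         noise_floor = params$noise_floor)
  if (length(ap_idx) == 0L) {
    return(event_series(numeric(0), "cycle", params$min_interval_s))
  }
  ap_t <- rec$time_s[ap_idx]
  cand_t <- rec$time_s[as.integer(cand)]
  confirmed <- vapply(cand_t, function(tt) {
    min(abs(ap_t - tt)) <= params$confirm_window_s
  }, logical(1))
  kept <- refractory_thin(as.integer(cand)[confirmed],
                          attr(cand, "prominence")[confirmed],
                          params$min_interval_s * fs)
  event_series(rec$time_s[kept], "cycle", params$min_interval_s)
}

#' Detect running strides
#'
#' Counts peaks only (no troughs) of the low-pass-filtered vertical
#' accelerometer channel; each retained impact peak is one stride.
#'
#' @inheritParams detect_swim_strokes
#' @return An [event_series()].
#' @export
detect_run_strides <- function(rec, params = default_detection_params("run")) {
  det <- detect_on_channel(rec, "acc_v", params, "peaks")
  event_series(det$times, "run", params$min_interval_s)
}

#' Detect events for any discipline
#'
#' Dispatches to the discipline-specific detector.
#'
#' @param rec An [imu_recording()].
#' @param discipline `"swim"`, `"cycle"` or `"run"`; defaults to the
#'   recording's own label.
#' @param params Optional [detection_params()].
#' @return An [event_series()].
#' @export
detect_events <- function(rec, discipline = attr(rec, "discipline"),
                          params = NULL) {
  discipline <- match.arg(discipline, c("swim", "cycle", "run"))
  params <- params %||% default_detection_params(discipline)
  switch(discipline,
         swim = detect_swim_strokes(rec, params),
         cycle = detect_cycle_pedal_strokes(rec, params),
         run = detect_run_strides(rec, params))
}
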