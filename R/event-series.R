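#' Construct an event series
#'
#' Timestamps of detected (or ground-truth) propulsive events — swimming
#' strokes, pedal strokes or running strides.
#'
#' @param event_times_s Strictly increasing event timestamps in seconds.
#' @param discipline `"swim"`, `"cycle"`, `"run"` or `"unknown"`.
#' @param min_interval_s Refractory interval used at detection (NA for
#'   ground truth).
#' @return An object of class `event_series`.
#' @export
event_series <- function(event_times_s, discipline = "unknown",
                         min_interval_s = NA_real_) {
  discipline <- match.arg(discipline, c("swim", "cycle", "run", "unknown"))
  event_times_s <- as.numeric(event_times_s)
  if (length(event_times_s) > 1L && any(diff(event_times_s) <= 0)) {
    tri_abort("event times must be strictly increasing", "invalid_config")
  }
  structure(list(event_times_s = event_times_s,
                 discipline = discipline,
                 count = length(event_times_s),
                 min_interval_s = min_interval_s),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s, %d events", x$discipline, x$count))
  if (x$count > 1L) {
    cat(sprintf(" over %.1f s (mean rate %.1f /min)",
                diff(range(x$event_times_s)),
                60 * (x$count - 1) / diff(range(x$event_times_s))))
  }
  cat("\n")
  invisible(x)
}

#' Average cadence of an event series
#'
#' Cadence is the number of propulsive events per minute over the recording:
#' `60 * count / duration_s`.
#'
#' @param events An [event_series()].
#' @param duration_s Recording duration in seconds (> 0).
#' @return Cadence in events/min.
#' @export
average_cadence <- function(events, duration_s) {
  if (!is_scalar_num(duration_s) || duration_s <= 0) {
    tri_abort("duration_s must be > 0", "invalid_parameter")
  }
  60 * events$count / duration_s
}

#' Write an event series as CSV
#' @param events An [event_series()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  write.csv(data.frame(event_time_s = events$event_times_s), path,
            row.names = FALSE)
  invisible(path)
}
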