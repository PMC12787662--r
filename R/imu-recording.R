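#' Construct an IMU recording
#'
#' A recording is a data frame with one row per sample holding synchronized
#' tri-axial accelerometer (m/s^2) and gyroscope (deg/s) channels from a
#' trunk-worn sensor. Channel names follow the body-referenced convention:
#' `acc_ml` (medio-lateral), `acc_ap` (antero-posterior), `acc_v` (vertical),
#' and `gyr_yaw`, `gyr_roll`, `gyr_pitch`.
#'
#' @param time_s Strictly increasing, uniformly spaced timestamps in seconds.
#' @param acc_ml,acc_ap,acc_v Acceleration channels (m/s^2).
#' @param gyr_yaw,gyr_roll,gyr_pitch Angular-velocity channels (deg/s).
#' @param sample_rate_hz Sampling rate in Hz; `time_s` must be consistent
#'   with it to within 1e-6 s per step.
#' @param discipline `"swim"`, `"cycle"`, `"run"` or `"unknown"`.
#' @return An object of class `imu_recording` (a data frame with attributes
#'   `sample_rate_hz` and `discipline`).
#' @export
imu_recording <- function(time_s, acc_ml, acc_ap, acc_v,
                          gyr_yaw, gyr_roll, gyr_pitch,
                          sample_rate_hz, discipline = "unknown") {
  check_scalar(sample_rate_hz, "sample_rate_hz", lower = 0, strict_lower = TRUE)
  discipline <- match.arg(discipline, c("swim", "cycle", "run", "unknown"))
  chans <- list(time_s = time_s, acc_ml = acc_ml, acc_ap = acc_ap,
                acc_v = acc_v, gyr_yaw = gyr_yaw, gyr_roll = gyr_roll,
                gyr_pitch = gyr_pitch)
  n <- length(time_s)
  if (n == 0L) tri_abort("recording has no samples", "degenerate_input")
  len_ok <- vapply(chans, length, 0L) == n
  if (!all(len_ok)) {
    tri_abort("all channels must have the same length as time_s",
              "invalid_config")
  }
  if (n > 1L) {
    dt <- diff(time_s)
    if (any(abs(dt - 1 / sample_rate_hz) > 1e-6)) {
      tri_abort("time_s must be uniform at 1/sample_rate_hz spacing",
                "invalid_config")
    }
  }
  rec <- as.data.frame(chans)
  attr(rec, "sample_rate_hz") <- sample_rate_hz
  attr(rec, "discipline") <- discipline
  class(rec) <- c("imu_recording", "data.frame")
  rec
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s, %d samples @ %g Hz (%.1f s)\n",
              attr(x, "discipline"), nrow(x), attr(x, "sample_rate_hz"),
              nrow(x) / attr(x, "sample_rate_hz")))
  invisible(x)
}

#' Sampling rate of a recording
#' @param rec An [imu_recording()].
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(rec) attr(rec, "sample_rate_hz")

rec_channel <- function(rec, channel) {
  x <- rec[[channel]]
  if (is.null(x) || all(is.na(x))) {
    tri_abort(sprintf("recording has no usable `%s` channel", channel),
              "missing_channel")
  }
  x
}

#' Write / read an IMU recording as CSV
#'
#' The file carries a `#`-prefixed metadata line (sampling rate, discipline,
#' units) followed by a header row and the seven channel columns.
#'
#' @param rec An [imu_recording()].
#' @param path File path.
#' @return `write_imu_csv` returns `path` invisibly; `read_imu_csv` returns
#'   an [imu_recording()].
#' @export
write_imu_csv <- function(rec, path) {
  meta <- sprintf(
    "# sample_rate_hz=%g discipline=%s acc_units=m/s^2 gyr_units=deg/s",
    attr(rec, "sample_rate_hz"), attr(rec, "discipline"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(as.data.frame(rec), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  first <- readLines(path, n = 1L)
  rate <- 100
  disc <- "unknown"
  if (startsWith(first, "#")) {
    toks <- strsplit(trimws(sub("^#", "", first)), "\\s+")[[1]]
    kv <- strsplit(toks, "=")
    for (p in kv) {
      if (length(p) == 2L && p[[1]] == "sample_rate_hz") rate <- as.numeric(p[[2]])
      if (length(p) == 2L && p[[1]] == "discipline") disc <- p[[2]]
    }
  }
  d <- read.csv(path, comment.char = "#")
  imu_recording(d$time_s, d$acc_ml, d$acc_ap, d$acc_v,
                d$gyr_yaw, d$gyr_roll, d$gyr_pitch,
                sample_rate_hz = rate, discipline = disc)
}
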