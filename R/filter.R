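#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (`signal::filtfilt`), so the output has no phase lag and the effective
#' magnitude response is the squared single-pass Butterworth response
#' `|H(f)|^2 = 1 / (1 + (f / cutoff_hz)^(2 * order))`.
#'
#' @param x Numeric signal.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param cutoff_hz Low-pass corner frequency in Hz (must be below the
#'   Nyquist frequency).
#' @param order Filter order (even positive integer, default 4).
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, sample_rate_hz, cutoff_hz, order = 4) {
  check_scalar(sample_rate_hz, "sample_rate_hz", lower = 0,
               strict_lower = TRUE, class = "invalid_parameter")
  check_scalar(cutoff_hz, "cutoff_hz", lower = 0, strict_lower = TRUE,
               class = "invalid_parameter")
  if (cutoff_hz >= sample_rate_hz / 2) {
    tri_abort("cutoff_hz must be below the Nyquist frequency",
              "invalid_parameter")
  }
  if (!is_scalar_num(order) || order < 2 || order %% 2 != 0) {
    tri_abort("order must be an even integer >= 2", "invalid_parameter")
  }
  if (length(x) <= 3 * order) {
    tri_abort("signal too short for the requested filter order",
              "degenerate_input")
  }
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), type = "low")
  # reflect the signal (odd extension) at both ends before the
  # forward-backward pass so filter start-up transients fall outside the
  # retained segment; the pad covers several settling times of the filter
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * sample_rate_hz / cutoff_hz))
  head_ext <- 2 * x[[1L]] - x[(pad + 1L):2L]
  tail_ext <- 2 * x[[n]] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(head_ext, x, tail_ext))
  as.numeric(y[(pad + 1L):(pad + n)])
}
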