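# Local-extremum detection with topographic prominence and
# refractory-interval thinning.

# Indices of strict local maxima; plateaus report their first sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  s <- sign(diff(x))
  # carry the previous non-zero slope through plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  s <- s[nz]
  pos <- which(nz)
  idx <- which(s[-length(s)] > 0 & s[-1L] < 0)
  if (length(idx) == 0L) return(integer(0))
  pos[idx] + 1L
}

# Topographic prominence of the peaks at `peaks` (indices into x): height
# above the higher of the two lowest saddles separating the peak from the
# nearest higher ground on each side.  A side whose scan reaches the
# record boundary without meeting higher ground does not constrain the
# prominence (the record merely truncates the field of view there), so
# extrema near the boundaries keep their full prominence; the global
# maximum falls back to height above the overall minimum.
peak_prominences <- function(x, peaks) {
  n <- length(x)
  prom <- numeric(length(peaks))
  for (p in seq_along(peaks)) {
    i <- peaks[[p]]
    h <- x[[i]]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[[j]] <= h) {
      if (x[[j]] < lmin) lmin <- x[[j]]
      j <- j - 1L
    }
    l_open <- j < 1L
    rmin <- h
    j <- i + 1L
    while (j <= n && x[[j]] <= h) {
      if (x[[j]] < rmin) rmin <- x[[j]]
      j <- j + 1L
    }
    r_open <- j > n
    base <- if (l_open && r_open) min(lmin, rmin) else
      if (l_open) rmin else if (r_open) lmin else max(lmin, rmin)
    prom[[p]] <- h - base
  }
  prom
}

# Greedy refractory thinning: process candidates in order of decreasing
# prominence (ties -> earlier sample); a candidate is kept only if no kept
# event lies within min_gap samples.
refractory_thin <- function(idx, prom, min_gap) {
  if (length(idx) <= 1L) return(idx)
  ord <- order(-prom, idx)
  kept <- integer(0)
  for (k in ord) {
    if (length(kept) == 0L || all(abs(kept - idx[[k]]) >= min_gap)) {
      kept <- c(kept, idx[[k]])
    }
  }
  sort(kept)
}

#' Find prominent local extrema with refractory thinning
#'
#' Detects local maxima (and, in `peaks_and_troughs` mode, minima) whose
#' topographic prominence exceeds a threshold, then greedily thins them so
#' that no two retained events of any kind are closer than `min_interval_s`;
#' when two candidates conflict, the one with the larger prominence is kept
#' (ties broken toward the earlier sample). Extrema near the record
#' boundaries are retained if they satisfy the prominence rule.
#'
#' The prominence threshold is
#' `max(prominence_frac * robust_amplitude, noise_floor)`, where the robust
#' amplitude is the 1%-99% inter-quantile range of the signal — a
#' peak-to-peak scale that remains meaningful both for sustained
#' oscillations and for sparse impact trains. `noise_floor` is an absolute
#' floor (channel units) that silences channels carrying only low-level
#' noise.
#'
#' @param x Numeric signal (normally already low-pass filtered).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param min_interval_s Refractory interval in seconds.
#' @param prominence_frac Fraction of the robust amplitude required as
#'   prominence (default 0.2).
#' @param mode `"peaks"` or `"peaks_and_troughs"`.
#' @param noise_floor Absolute minimum prominence (default 0).
#' @return Integer vector of retained extremum indices (sorted), with a
#'   `"type"` attribute of `+1` (peak) / `-1` (trough) per index.
#' @export
find_extrema <- function(x, sample_rate_hz, min_interval_s,
                         prominence_frac = 0.2,
                         mode = c("peaks", "peaks_and_troughs"),
                         noise_floor = 0) {
  mode <- match.arg(mode)
  if (length(x) == 0L) {
    tri_abort("empty signal", "degenerate_input")
  }
  check_scalar(min_interval_s, "min_interval_s", lower = 0,
               class = "invalid_parameter")
  amp <- as.numeric(quantile(x, 0.99, names = FALSE) -
                      quantile(x, 0.01, names = FALSE))
  thr <- max(prominence_frac * amp, noise_floor)

  pk <- local_maxima(x)
  pk_prom <- peak_prominences(x, pk)
  keep <- pk_prom >= thr
  idx <- pk[keep]
  prom <- pk_prom[keep]
  type <- rep(1L, length(idx))
  if (mode == "peaks_and_troughs") {
    tr <- local_maxima(-x)
    tr_prom <- peak_prominences(-x, tr)
    keep <- tr_prom >= thr
    idx <- c(idx, tr[keep])
    prom <- c(prom, tr_prom[keep])
    type <- c(type, rep(-1L, sum(keep)))
    o <- order(idx)
    idx <- idx[o]; prom <- prom[o]; type <- type[o]
  }
  min_gap <- min_interval_s * sample_rate_hz
  kept <- refractory_thin(idx, prom, min_gap)
  out <- kept
  m <- match(kept, idx)
  attr(out, "type") <- type[m]
  attr(out, "prominence") <- prom[m]
  out
}
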