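#' Predicted cadence curve with 95% confidence intervals
#'
#' Evaluates the fitted population cadence curve on a week grid. At the
#' group level the random effects are set to zero and the pointwise 95%
#' confidence band is `prediction +/- 1.96 * SE`, with the SE taken from
#' the coefficient covariance of the fixed and smooth terms. At the
#' individual level each athlete's `b0_i + b1_i * W` is added, giving one
#' trajectory per athlete (pooled towards the population mean by the
#' random-effect shrinkage).
#'
#' Weeks outside the observed range are allowed but flagged with a
#' warning and an `extrapolated` attribute.
#'
#' @param fit A [fit_model()] result.
#' @param weeks Numeric evaluation grid.
#' @param season Season level to predict for (default: reference season).
#' @param level `"group"` or `"individual"`.
#' @return A data frame of class `cadence_curve` with columns `week`,
#'   `mean`, `lo95`, `hi95`; when `level = "individual"` an `individual`
#'   attribute holds a weeks-by-athletes matrix of trajectories. When the
#'   grid step is one week, a `pct_change` attribute holds the per-week
#'   percentage change of the population mean.
#' @export
predict_curve <- function(fit, weeks, season = NULL,
                          level = c("group", "individual")) {
  level <- match.arg(level)
  if (!is.numeric(weeks) || length(weeks) == 0L) {
    tri_abort("weeks grid must be numeric", "invalid_parameter")
  }
  weeks <- as.numeric(weeks)
  extrap <- any(weeks < fit$week_range[[1L]] - 1e-9) ||
    any(weeks > fit$week_range[[2L]] + 1e-9)
  if (extrap) {
    warning("prediction grid extends beyond the observed week range")
  }
  p <- length(fit$coefficients)
  ng <- length(weeks)
  Xg <- matrix(0, ng, p)
  Xg[, fit$idx$intercept] <- 1
  if (!is.null(fit$idx$season)) {
    s2 <- 0
    if (!is.null(season)) {
      season <- as.character(season)
      if (!season %in% fit$season_levels) {
        tri_abort("unknown season level", "invalid_parameter")
      }
      s2 <- as.numeric(season == fit$season_levels[[2L]])
    }
    Xg[, fit$idx$season] <- s2
  }
  if (!is.null(fit$idx$week)) Xg[, fit$idx$week] <- weeks
  if (!is.null(fit$idx$smooth)) {
    Xg[, fit$idx$smooth] <- tprs_eval(fit$basis, weeks)
  }
  mean_curve <- (Xg %*% fit$coefficients)[, 1L]
  se <- sqrt(pmax(rowSums((Xg %*% fit$Vb) * Xg), 0))
  out <- data.frame(week = weeks, mean = mean_curve,
                    lo95 = mean_curve - 1.96 * se,
                    hi95 = mean_curve + 1.96 * se)
  class(out) <- c("cadence_curve", "data.frame")
  attr(out, "extrapolated") <- extrap
  if (level == "individual") {
    np <- length(fit$pid_levels)
    ind <- matrix(NA_real_, ng, np,
                  dimnames = list(NULL, fit$pid_levels))
    for (j in seq_len(np)) {
      add <- 0
      if (!is.null(fit$b0)) add <- add + fit$b0[[j]]
      if (!is.null(fit$b1)) add <- add + fit$b1[[j]] * weeks
      ind[, j] <- mean_curve + add
    }
    attr(out, "individual") <- ind
  }
  if (ng > 1L && all(abs(diff(weeks) - 1) < 1e-9) && all(mean_curve != 0)) {
    attr(out, "pct_change") <- weekly_percent_change(out)$per_week
  }
  out
}

#' Weekly percentage change of a predicted cadence curve
#'
#' Between successive weeks on a one-week grid,
#' `pct[w] = 100 * (mean[w+1] - mean[w]) / mean[w]`; the window summary is
#' the arithmetic mean of the per-week changes whose starting week lies in
#' `[window[1], window[2] - 1]`.
#'
#' @param curve A [predict_curve()] result (or data frame with `week` and
#'   `mean`), on a one-week grid within the window.
#' @param window Optional `c(first_week, last_week)` interval; default the
#'   whole grid.
#' @return List with `per_week` (named vector of percentage changes,
#'   labelled by starting week) and `window_mean`.
#' @export
weekly_percent_change <- function(curve, window = NULL) {
  w <- curve$week
  m <- curve$mean
  window <- window %||% range(w)
  sel <- which(w >= window[[1L]] - 1e-9 & w <= window[[2L]] + 1e-9)
  if (length(sel) < 2L) {
    tri_abort("window must contain at least two grid weeks",
              "invalid_parameter")
  }
  w <- w[sel]; m <- m[sel]
  if (any(abs(diff(w) - 1) > 1e-9)) {
    tri_abort("percentage change requires a one-week grid step",
              "invalid_parameter")
  }
  if (any(m[-length(m)] == 0)) {
    tri_abort("curve mean of zero makes the ratio undefined",
              "undefined_ratio")
  }
  pct <- 100 * diff(m) / m[-length(m)]
  names(pct) <- w[-length(w)]
  list(per_week = pct, window_mean = mean(pct))
}

#' Write a prediction curve as CSV
#' @param curve A [predict_curve()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(as.data.frame(curve)[, c("week", "mean", "lo95", "hi95")],
            path, row.names = FALSE)
  invisible(path)
}
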