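#' Compare the linear and non-linear cadence models
#'
#' Likelihood-ratio comparison of two models fitted to the same data:
#' `D = 2 * (loglik_nonlinear - loglik_linear)` (clipped at 0), referred to
#' a chi-squared distribution with `df = max(edf_nl - edf_lin, 0.5)`
#' degrees of freedom (the difference in total effective degrees of
#' freedom, floored at 0.5).
#'
#' The log-likelihoods entering `D` are *marginal* maximum likelihoods:
#' each model's penalized coefficient blocks (the week smooth and the
#' random effects) are integrated out and its smoothing/precision
#' parameters re-optimized under the marginal ML criterion. Conditional
#' log-likelihoods at the penalized fits are not comparable between models
#' with different fixed-effect structure and give a likelihood-ratio
#' statistic with no usable chi-squared reference, whereas the marginal ML
#' ratio is the standard test for nested mixed models. Because the null
#' hypothesis places variance parameters on the boundary of their space,
#' the chi-squared reference is still approximate; the result carries a
#' `boundary_approx` flag noting this. AIC, BIC and adjusted r-squared of
#' both fits are copied in.
#'
#' @param fit_lin,fit_nl Fits from [fit_model()] on the same data (the
#'   linear and non-linear specification respectively).
#' @return An object of class `cadence_model_comparison` with fields `D`,
#'   `df`, `p`, `aic_linear`, `aic_nonlinear`, `bic_linear`,
#'   `bic_nonlinear`, `r2_linear`, `r2_nonlinear`.
#' @export
compare_models <- function(fit_lin, fit_nl) {
  if (!inherits(fit_lin, "cadence_gam") || !inherits(fit_nl, "cadence_gam")) {
    tri_abort("both arguments must be cadence_gam fits", "invalid_parameter")
  }
  if (fit_lin$n != fit_nl$n ||
      !isTRUE(all.equal(fit_lin$y, fit_nl$y, tolerance = 1e-12))) {
    tri_abort("fits were not produced from the same data",
              "incomparable_fits")
  }
  D <- max(0, 2 * (marginal_loglik(fit_nl) - marginal_loglik(fit_lin)))
  df <- max(fit_nl$edf_total - fit_lin$edf_total, 0.5)
  p <- pchisq(D, df, lower.tail = FALSE)
  structure(list(D = D, df = df, p = p,
                 aic_linear = fit_lin$aic, aic_nonlinear = fit_nl$aic,
                 bic_linear = fit_lin$bic, bic_nonlinear = fit_nl$bic,
                 r2_linear = fit_lin$r2_adj, r2_nonlinear = fit_nl$r2_adj,
                 boundary_approx = TRUE),
            class = "cadence_model_comparison")
}

#' @export
print.cadence_model_comparison <- function(x, ...) {
  cat("<model comparison> linear vs non-linear\n")
  cat(sprintf("  AIC  %.2f vs %.2f\n", x$aic_linear, x$aic_nonlinear))
  cat(sprintf("  BIC  %.2f vs %.2f\n", x$bic_linear, x$bic_nonlinear))
  cat(sprintf("  r2   %.3f vs %.3f\n", x$r2_linear, x$r2_nonlinear))
  cat(sprintf("  D = %.3f on %.2f df, p = %.4g%s\n", x$D, x$df, x$p,
              if (isTRUE(x$boundary_approx))
                "  (boundary chi-squared approximation)" else ""))
  invisible(x)
}

ks_statistic_normal <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - p), max(p - (i - 1) / n))
}

#' Kolmogorov-Smirnov normality check with Monte-Carlo calibration
#'
#' One-sample KS statistic of the data against a normal distribution with
#' sample-estimated mean and SD. Because the parameters are estimated from
#' the same sample, the naive KS null distribution is wrong; the p-value
#' is therefore calibrated by seeded Monte-Carlo simulation
#' (Lilliefors-style): the statistic is recomputed on `B` normal samples
#' of the same size, each standardized by its own estimates.
#'
#' @param values Numeric sample (n >= 5, nonzero variance).
#' @param B Number of Monte-Carlo replicates (default 2000).
#' @param seed Integer seed for the calibration draws (default 1).
#' @return List with `statistic` and `p`.
#' @export
ks_normality <- function(values, B = 2000, seed = 1) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 5L) tri_abort("need at least 5 values", "degenerate_input")
  if (sd(values) == 0) {
    tri_abort("sample is constant; normality check is undefined",
              "degenerate_input")
  }
  D <- ks_statistic_normal(values)
  Db <- with_seed(seed, {
    vapply(seq_len(B), function(b) ks_statistic_normal(rnorm(n)), 0)
  })
  list(statistic = D, p = (1 + sum(Db >= D)) / (B + 1))
}
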