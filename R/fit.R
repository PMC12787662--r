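# Penalized-regression formulation of the season cadence models.
#
# Both models are fitted as Gaussian penalized least squares with the
# smoothing / precision parameters chosen by restricted maximum likelihood:
#
#   linear:     C = beta0 + beta1*W + beta2*season2 + b0_i + b1_i*W + eps
#   non-linear: C = beta0 + f(W)    + beta2*season2 + b0_i + b1_i*W + eps
#
# f(W) is a rank-reduced thin-plate regression spline.  Random intercepts
# and slopes are ridge-penalized indicator blocks (random-effect smooths),
# equivalent to b0_i ~ N(0, sigma^2/lambda_b0) etc.  The smooth carries a
# double penalty: its range part under the spline penalty and its
# null-space (linear) part under a separate shrinkage penalty, so the
# estimated degrees of freedom of f can approach zero when the data carry
# no common trend.
#
# For coefficients beta minimizing ||y - X beta||^2 + sum_j lambda_j
# beta' S_j beta, the restricted likelihood profiled over sigma^2 is
#   -2 l_r = (n - M_p) (log(2 pi phi) + 1) + log|X'X + S_lambda|
#            - log|S_lambda|_+
# with phi = (||y - X b||^2 + b' S_lambda b) / (n - M_p) and M_p the
# dimension of the unpenalized space.  This criterion is minimized over
# log-smoothing parameters from three fixed starts.

#' Model design specification
#'
#' @param model_type `"linear"` or `"nonlinear"`.
#' @param k_basis Thin-plate basis dimension for the week smooth
#'   (default 10, >= 3; nonlinear model only).
#' @param random_intercept,random_slope Include per-athlete random
#'   intercepts / random slopes of week (both default TRUE).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(model_type = c("nonlinear", "linear"), k_basis = 10,
                        random_intercept = TRUE, random_slope = TRUE) {
  model_type <- match.arg(model_type)
  if (!is_scalar_num(k_basis) || k_basis < 3) {
    tri_abort("k_basis must be >= 3", "invalid_parameter")
  }
  structure(list(model_type = model_type, k_basis = as.integer(k_basis),
                 random_intercept = isTRUE(random_intercept),
                 random_slope = isTRUE(random_slope)),
            class = "design_spec")
}

build_design <- function(data, spec) {
  need <- c("cadence", "week", "participant_id")
  if (!all(need %in% names(data))) {
    tri_abort("data needs columns cadence, week, participant_id",
              "invalid_config")
  }
  y <- as.numeric(data$cadence)
  n <- length(y)
  week <- as.numeric(data$week)
  pid <- factor(data$participant_id)
  n_p <- nlevels(pid)
  if ((spec$random_intercept || spec$random_slope) && n_p < 2L) {
    tri_abort("mixed-model fitting needs at least 2 participants",
              "insufficient_support")
  }
  season <- if (is.null(data$season)) factor(rep(1L, n)) else {
    factor(data$season)
  }

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  idx <- list(intercept = 1L)
  if (nlevels(season) > 1L) {
    if (nlevels(season) > 2L) {
      tri_abort("at most two seasons are supported", "invalid_config")
    }
    X <- cbind(X, season2 = as.numeric(season == levels(season)[[2L]]))
    idx$season <- ncol(X)
  }
  pen <- list()
  basis <- NULL
  if (spec$model_type == "linear") {
    X <- cbind(X, week = week)
    idx$week <- ncol(X)
  } else {
    basis <- tprs_basis(week, spec$k_basis)
    Xs <- tprs_eval(basis, week)
    sidx <- ncol(X) + seq_len(ncol(Xs))
    X <- cbind(X, Xs)
    idx$smooth <- sidx
    kr <- ncol(Xs) - 1L  # range columns
    pen$smooth_range <- list(cols = sidx[seq_len(kr)], S = basis$S_range,
                             rank = basis$rank, ldS = basis$ldS)
    pen$smooth_null <- list(cols = sidx[[kr + 1L]],
                            S = diag(1), rank = 1L, ldS = 0)
  }
  Zind <- matrix(0, n, n_p)
  Zind[cbind(seq_len(n), as.integer(pid))] <- 1
  if (spec$random_intercept) {
    Z0 <- Zind
    colnames(Z0) <- paste0("b0:", levels(pid))
    cols <- ncol(X) + seq_len(n_p)
    X <- cbind(X, Z0)
    idx$b0 <- cols
    pen$b0 <- list(cols = cols, S = diag(n_p), rank = n_p, ldS = 0)
  }
  if (spec$random_slope) {
    Z1 <- Zind * week
    colnames(Z1) <- paste0("b1:", levels(pid))
    cols <- ncol(X) + seq_len(n_p)
    X <- cbind(X, Z1)
    idx$b1 <- cols
    pen$b1 <- list(cols = cols, S = diag(n_p), rank = n_p, ldS = 0)
  }
  list(y = y, X = X, idx = idx, pen = pen, basis = basis,
       pid_levels = levels(pid), pid = pid, week = week, season = season,
       season_levels = levels(season))
}

penalty_total <- function(pen, lambda, p) {
  S <- matrix(0, p, p)
  for (j in seq_along(pen)) {
    cols <- pen[[j]]$cols
    S[cols, cols] <- S[cols, cols] + lambda[[j]] * pen[[j]]$S
  }
  S
}

reml_criterion <- function(rho, XtX, Xty, yty, pen, n) {
  p <- ncol(XtX)
  lambda <- exp(pmin(pmax(rho, -30), 30))
  H <- XtX + penalty_total(pen, lambda, p)
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) {
    R <- tryCatch(chol(H + diag(1e-8 * mean(diag(H)), p)),
                  error = function(e) NULL)
    if (is.null(R)) return(1e15)
  }
  beta <- backsolve(R, forwardsolve(t(R), Xty))
  Dp <- max(yty - sum(beta * Xty), 1e-12)
  Mp <- p - sum(vapply(pen, function(b) b$rank, 0L))
  phi <- Dp / (n - Mp)
  ldH <- 2 * sum(log(diag(R)))
  ldS <- sum(vapply(seq_along(pen), function(j) {
    pen[[j]]$rank * rho[[j]] + pen[[j]]$ldS
  }, 0))
  val <- (n - Mp) * (log(2 * pi * phi) + 1) + ldH - ldS
  # soft barrier keeps the optimizer inside the clamped region
  val + 10 * sum(pmax(abs(rho) - 25, 0)^2)
}

# Marginal maximum-likelihood criterion (-2 log marginal likelihood up to
# the flat-prior fixed effects, profiled over sigma^2): the penalized
# coefficient blocks are integrated out as mean-zero Gaussians with
# covariance sigma^2 / lambda_j * S_j^-1, the unpenalized fixed effects are
# profiled.  Unlike the restricted criterion, this one is comparable
# between models with different fixed-effect structure, so it is the
# likelihood used for the linear-versus-smooth likelihood-ratio test.
ml_criterion <- function(rho, XtX, Xty, yty, pen, n) {
  p <- ncol(XtX)
  lambda <- exp(pmin(pmax(rho, -30), 30))
  S <- penalty_total(pen, lambda, p)
  H <- XtX + S
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) return(1e15)
  beta <- backsolve(R, forwardsolve(t(R), Xty))
  Dp <- max(yty - sum(beta * Xty), 1e-12)
  pcols <- sort(unique(unlist(lapply(pen, function(b) b$cols))))
  A <- XtX[pcols, pcols, drop = FALSE] + S[pcols, pcols, drop = FALSE]
  Ra <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Ra)) return(1e15)
  ldA <- 2 * sum(log(diag(Ra)))
  ldS <- sum(vapply(seq_along(pen), function(j) {
    pen[[j]]$rank * rho[[j]] + pen[[j]]$ldS
  }, 0))
  val <- n * (log(2 * pi * Dp / n) + 1) + ldA - ldS
  val + 10 * sum(pmax(abs(rho) - 25, 0)^2)
}

# Maximized marginal log-likelihood of a fitted model (lazy, cached):
# re-optimizes the smoothing/precision parameters under the ML criterion,
# started from the REML estimates and the fixed starts.
marginal_loglik <- function(fit) {
  if (!is.null(fit$loglik_ml)) return(fit$loglik_ml)
  XtX <- crossprod(fit$X)
  Xty <- crossprod(fit$X, fit$y)[, 1L]
  yty <- sum(fit$y^2)
  m <- length(fit$pen)
  n <- fit$n
  if (m == 0L) return(fit$loglik)
  starts <- list(log(pmax(fit$lambdas, 1e-12)), rep(0, m), rep(4, m))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, ml_criterion, XtX = XtX, Xty = Xty, yty = yty,
            pen = fit$pen, n = n, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    tri_abort("ML optimization failed from all starts", "convergence")
  }
  -best$value / 2
}

#' Fit a season cadence model
#'
#' Fits the linear or non-linear (penalized thin-plate smooth) mixed model
#' of average cadence on week number by penalized least squares, with the
#' smoothing parameter and the random-intercept/random-slope precisions
#' estimated by restricted maximum likelihood (three fixed optimizer
#' starts, Nelder-Mead on the log-parameters). Individual trajectories are
#' shrunk towards the population mean by the random-effect penalties.
#'
#' @param data Data frame with columns `cadence`, `week`,
#'   `participant_id` and optionally `season` (a factor or 1/2 coding;
#'   season 1 is the reference level).
#' @param spec A [design_spec()].
#' @param lambdas Optional numeric vector of fixed smoothing/precision
#'   parameters (one per penalty, in the order smooth-range, smooth-null,
#'   random-intercept, random-slope, as applicable); when supplied the
#'   REML optimization is skipped. Mainly for nesting and sensitivity
#'   checks.
#' @return An object of class `cadence_gam` carrying the population
#'   coefficients (`beta0`, `beta1`, `beta2`), smooth coefficients,
#'   per-athlete random effects (`b0`, `b1`), variance components
#'   (`var_b0`, `var_b1`, `var_eps`), smoothing parameters, effective
#'   degrees of freedom (`edf_smooth`, `edf_total`), conditional
#'   log-likelihood, REML score, AIC/BIC, adjusted r-squared, fitted
#'   values and prediction internals.
#' @export
fit_model <- function(data, spec = design_spec("nonlinear"), lambdas = NULL) {
  if (!inherits(spec, "design_spec")) {
    tri_abort("spec must be a design_spec", "invalid_parameter")
  }
  des <- build_design(data, spec)
  y <- des$y
  X <- des$X
  n <- length(y)
  p <- ncol(X)
  if (n <= p - sum(vapply(des$pen, function(b) b$rank, 0L))) {
    tri_abort("too few observations for the unpenalized terms",
              "insufficient_support")
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1L]
  yty <- sum(y^2)
  m <- length(des$pen)

  conv <- TRUE
  if (m == 0L) {
    rho <- numeric(0)
    reml <- NA_real_
  } else if (!is.null(lambdas)) {
    if (length(lambdas) != m) {
      tri_abort(sprintf("lambdas must have length %d for this design", m),
                "invalid_parameter")
    }
    rho <- log(pmax(lambdas, 1e-300))
    reml <- reml_criterion(rho, XtX, Xty, yty, des$pen, n) / 2
  } else {
    starts <- list(rep(0, m), rep(4, m), rep(-4, m))
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        optim(s, reml_criterion, XtX = XtX, Xty = Xty, yty = yty,
              pen = des$pen, n = n, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) {
      tri_abort("REML optimization failed from all starts", "convergence")
    }
    rho <- best$par
    reml <- best$value / 2
    conv <- best$convergence == 0
    if (!conv) {
      warning("REML optimizer hit its iteration limit; result may be inexact")
    }
  }

  lambda <- if (m > 0) exp(pmin(pmax(rho, -30), 30)) else numeric(0)
  names(lambda) <- names(des$pen)
  H <- XtX + penalty_total(des$pen, lambda, p)
  R <- tryCatch(chol(H), error = function(e) {
    tri_abort("singular penalized design (rank deficiency)",
              "rank_deficiency")
  })
  Hinv <- chol2inv(R)
  beta <- (Hinv %*% Xty)[, 1L]
  names(beta) <- colnames(X)
  fitted <- (X %*% beta)[, 1L]
  rss <- sum((y - fitted)^2)
  Dp <- rss + {
    Sb <- penalty_total(des$pen, lambda, p)
    sum(beta * (Sb %*% beta))
  }
  Mp <- p - sum(vapply(des$pen, function(b) b$rank, 0L))
  phi <- Dp / (n - Mp)
  edf_by_col <- rowSums(Hinv * XtX)
  edf_total <- sum(edf_by_col)
  edf_smooth <- if (is.null(des$idx$smooth)) 0 else {
    sum(edf_by_col[des$idx$smooth])
  }
  loglik <- -n / 2 * (log(2 * pi * rss / n) + 1)
  tss <- sum((y - mean(y))^2)
  r2_adj <- 1 - (rss / (n - edf_total)) / (tss / (n - 1))
  Vb <- phi * Hinv

  idx <- des$idx
  se <- sqrt(pmax(diag(Vb), 0))
  fit <- structure(list(
    spec = spec,
    beta0 = beta[[idx$intercept]],
    beta1 = if (!is.null(idx$week)) beta[[idx$week]] else NA_real_,
    beta2 = if (!is.null(idx$season)) beta[[idx$season]] else NA_real_,
    se_beta0 = se[[idx$intercept]],
    se_beta1 = if (!is.null(idx$week)) se[[idx$week]] else NA_real_,
    se_beta2 = if (!is.null(idx$season)) se[[idx$season]] else NA_real_,
    smooth_coefs = if (!is.null(idx$smooth)) beta[idx$smooth] else NULL,
    b0 = if (!is.null(idx$b0)) setNames(beta[idx$b0], des$pid_levels) else
      NULL,
    b1 = if (!is.null(idx$b1)) setNames(beta[idx$b1], des$pid_levels) else
      NULL,
    var_b0 = if (!is.null(idx$b0)) phi / lambda[["b0"]] else NA_real_,
    var_b1 = if (!is.null(idx$b1)) phi / lambda[["b1"]] else NA_real_,
    var_eps = phi,
    lambdas = lambda,
    edf_by_col = edf_by_col,
    edf_smooth = edf_smooth,
    edf_total = edf_total,
    loglik = loglik,
    reml_score = reml,
    aic = -2 * loglik + 2 * edf_total,
    bic = -2 * loglik + log(n) * edf_total,
    r2_adj = r2_adj,
    rss = rss,
    n = n,
    converged = conv,
    coefficients = beta,
    Vb = Vb,
    fitted = fitted,
    y = y,
    X = X,
    pen = des$pen,
    loglik_ml = NULL,
    idx = idx,
    basis = des$basis,
    pid_levels = des$pid_levels,
    season_levels = des$season_levels,
    week_range = range(des$week)),
    class = "cadence_gam")
  fit
}

#' @export
print.cadence_gam <- function(x, ...) {
  cat(sprintf("<cadence_gam> %s model, n = %d, %d athletes\n",
              x$spec$model_type, x$n, length(x$pid_levels)))
  cat(sprintf("  beta0 = %.3f (SE %.3f)", x$beta0, x$se_beta0))
  if (!is.na(x$beta1)) cat(sprintf(", beta1 = %.4f (SE %.4f)",
                                   x$beta1, x$se_beta1))
  if (!is.na(x$beta2)) cat(sprintf(", beta2 = %.3f (SE %.3f)",
                                   x$beta2, x$se_beta2))
  cat("\n")
  cat(sprintf("  sigma_b0 = %.3f, sigma_b1 = %.4f, sigma = %.3f\n",
              sqrt(max(x$var_b0, 0)), sqrt(max(x$var_b1, 0)),
              sqrt(x$var_eps)))
  cat(sprintf(
    "  eDF(smooth) = %.2f, eDF(total) = %.2f, AIC = %.2f, BIC = %.2f, adj r2 = %.3f\n",
    x$edf_smooth, x$edf_total, x$aic, x$bic, x$r2_adj))
  invisible(x)
}

#' Information criteria and fit statistics of a cadence model
#'
#' Recomputes `aic = -2 loglik + 2 edf_total`,
#' `bic = -2 loglik + log(n) edf_total` and
#' `r2_adj = 1 - (RSS / (n - edf_total)) / (TSS / (n - 1))` from a fitted
#' model, using the conditional log-likelihood at the fitted values and
#' the total effective degrees of freedom.
#'
#' @param fit A [fit_model()] result.
#' @param n_obs Number of observations (defaults to the fit's own n).
#' @return List with `aic`, `bic`, `r2_adj`.
#' @export
model_criteria <- function(fit, n_obs = fit$n) {
  if (n_obs <= fit$edf_total) {
    tri_abort("n_obs must exceed the total effective degrees of freedom",
              "ill_posed_criteria")
  }
  tss <- sum((fit$y - mean(fit$y))^2)
  list(aic = -2 * fit$loglik + 2 * fit$edf_total,
       bic = -2 * fit$loglik + log(n_obs) * fit$edf_total,
       r2_adj = 1 - (fit$rss / (n_obs - fit$edf_total)) /
         (tss / (length(fit$y) - 1)))
}
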