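test_that("with random effects disabled the fit equals ordinary least squares", {
  d6 <- ols_fixture()
  fo <- fit_model(d6, design_spec("linear", random_intercept = FALSE,
                                  random_slope = FALSE))
  ols <- lm(cadence ~ week, d6)
  expect_equal(c(fo$beta0, fo$beta1), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fo$edf_total, 2)
  expect_equal(fo$loglik, as.numeric(logLik(ols)), tolerance = 1e-10)
  # closed-form Gaussian AIC with p = 2 coefficients
  n <- nrow(d6)
  rss <- sum(residuals(ols)^2)
  expect_equal(fo$aic, n * (log(2 * pi * rss / n) + 1) + 2 * 2,
               tolerance = 1e-10)
})

test_that("flat-truth parameter recovery: slope null, intercept near truth", {
  g <- gen_season_dataset(season_gen_config(
    n_participants = 15, weeks = seq(0, 27, 3), trend_shape = "flat",
    beta0 = 60, sd_b0 = 0, sd_b1 = 0, sd_eps = 1.5, seed = 21))
  f <- fit_model(g$data, design_spec("linear"))
  expect_lt(abs(f$beta1) / f$se_beta1, 2)
  expect_lt(abs(f$beta0 - 60) / f$se_beta0, 2)
})

test_that("the smooth's effective df is non-increasing in lambda", {
  g <- season_fixture(seed = 13)
  lams <- 10^seq(-3, 6, by = 1.5)
  edfs <- sapply(lams, function(l) {
    f <- fit_model(g$data, design_spec("nonlinear"),
                   lambdas = c(l, 1e-6, 1, 1))
    f$edf_smooth
  })
  expect_true(all(diff(edfs) < 1e-8))
  expect_lt(edfs[[length(edfs)]], 1.5)  # collapses towards the line
})

test_that("sum of observation leverages equals the total effective df", {
  g <- season_fixture(seed = 17)
  f <- fit_model(g$data, design_spec("nonlinear"))
  XtX <- crossprod(f$X)
  H <- XtX + tricadence:::penalty_total(f$pen, f$lambdas, ncol(XtX))
  Hinv <- chol2inv(chol(H))
  lev <- rowSums((f$X %*% Hinv) * f$X)  # diag of the influence matrix
  expect_equal(sum(lev), f$edf_total, tolerance = 1e-6)
})

test_that("random slopes are pooled towards the population mean", {
  g <- gen_season_dataset(season_gen_config(
    n_participants = 10, weeks = seq(0, 27, 3), trend_shape = "flat",
    beta0 = 60, sd_b0 = 2, sd_b1 = 0.3, sd_eps = 2, seed = 31))
  f <- fit_model(g$data, design_spec("linear"))
  d <- g$data
  ids <- unique(d$participant_id)
  ols <- t(sapply(ids, function(id) {
    coef(lm(cadence ~ week, d[d$participant_id == id, ]))
  }))
  # penalized per-athlete effects are less dispersed than the raw
  # per-athlete least-squares estimates (pooling towards the mean), and
  # the athlete-specific deviations average out around zero
  expect_lt(sd(f$beta1 + f$b1), sd(ols[, "week"]))
  expect_lt(sd(f$beta0 + f$b0), sd(ols[, "(Intercept)"]))
  expect_lt(abs(mean(f$b1)), sd(ols[, "week"]))
  # each shrunken slope stays inside the span of the raw OLS slopes
  expect_true(all(f$beta1 + f$b1 >= min(ols[, "week"]) - 1e-8))
  expect_true(all(f$beta1 + f$b1 <= max(ols[, "week"]) + 1e-8))
})

test_that("smooth stays near-linear on linear-truth data across replicates", {
  # when the true trend is a straight line the penalized smooth should
  # collapse towards (at most) its linear null space in the large
  # majority of replicates; occasional spurious curvature from noise
  # shared across race weeks is intrinsic to REML selection (the
  # independent mixed-GAM cross-check flags the same replicates, with
  # equal or larger eDF)
  edfs <- sapply(1:50, function(s) {
    g <- gen_season_dataset(season_gen_config(
      trend_shape = "linear", beta1 = 0.12, seed = 800 + s))
    fit_model(g$data, design_spec("nonlinear"))$edf_smooth
  })
  expect_gte(mean(edfs <= 1.5), 0.8)
  expect_lte(median(edfs), 1)
})

test_that("fit agrees with an independent mixed-GAM implementation", {
  skip_if_not_installed("mgcv")
  g <- season_fixture(seed = 42)
  d <- g$data
  f <- fit_model(d, design_spec("nonlinear"))
  d$id <- factor(d$participant_id)
  m <- mgcv::gam(cadence ~ s(week, k = 10) + s(id, bs = "re") +
                   s(week, id, bs = "re"), data = d, method = "REML")
  expect_lt(sqrt(mean((fitted(m) - f$fitted)^2)), 0.05 * sd(d$cadence))
  expect_equal(sqrt(f$var_eps), sqrt(m$sig2), tolerance = 0.05)
  vc <- mgcv::gam.vcomp(m)
  expect_equal(sqrt(f$var_b0), vc["s(id)", "std.dev"], tolerance = 0.1)
  expect_equal(sqrt(f$var_b1), vc["s(week,id)", "std.dev"],
               tolerance = 0.15)
})

test_that("model criteria follow their definitions and nesting holds", {
  g <- season_fixture(seed = 23)
  f <- fit_model(g$data, design_spec("nonlinear"))
  crit <- model_criteria(f)
  expect_equal(crit$aic, -2 * f$loglik + 2 * f$edf_total)
  expect_equal(crit$bic, -2 * f$loglik + log(f$n) * f$edf_total)
  tss <- sum((f$y - mean(f$y))^2)
  expect_equal(crit$r2_adj,
               1 - (f$rss / (f$n - f$edf_total)) / (tss / (f$n - 1)))
  expect_error(model_criteria(f, n_obs = 3), class = "ill_posed_criteria")
  # a richer (barely penalized) model never has lower conditional loglik
  f_line <- fit_model(g$data, design_spec("linear",
                                          random_intercept = FALSE,
                                          random_slope = FALSE))
  f_rich <- fit_model(g$data, design_spec("nonlinear",
                                          random_intercept = FALSE,
                                          random_slope = FALSE),
                      lambdas = c(1e-8, 1e-8))
  expect_gte(f_rich$loglik, f_line$loglik - 1e-6)
})

test_that("r2_adj of a null-structure fit on centred noise is not clipped", {
  set.seed(4)
  d <- data.frame(cadence = rnorm(30), week = rep(0:9, 3),
                  participant_id = rep(c("A", "B", "C"), each = 10))
  f <- fit_model(d, design_spec("linear", random_intercept = FALSE,
                                random_slope = FALSE))
  expect_lt(f$r2_adj, 1)
  expect_true(is.finite(f$r2_adj))
})

test_that("fitting requires enough participants and valid specs", {
  d <- data.frame(cadence = rnorm(5, 60), week = 0:4,
                  participant_id = "solo")
  expect_error(fit_model(d, design_spec("linear")),
               class = "insufficient_support")
  expect_error(design_spec("nonlinear", k_basis = 2),
               class = "invalid_parameter")
})
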