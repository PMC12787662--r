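test_that("zero-noise flat truth yields a constant predicted curve at beta0", {
  g <- gen_season_dataset(season_gen_config(
    n_participants = 4, weeks = 0:10, trend_shape = "flat", beta0 = 60,
    beta2 = 2, sd_b0 = 0, sd_b1 = 0, sd_eps = 0, seasons = 2, seed = 1))
  f <- fit_model(g$data, design_spec("nonlinear"))
  cv <- predict_curve(f, 0:10)
  expect_equal(cv$mean, rep(60, 11), tolerance = 1e-6)
  cv2 <- predict_curve(f, 0:10, season = "2")
  expect_equal(cv2$mean, rep(62, 11), tolerance = 1e-6)
  expect_true(all(cv$lo95 <= cv$mean & cv$mean <= cv$hi95))
})

test_that("confidence bands are tighter where the design is dense", {
  # 0-5: ten athletes observed; 10-15: only two
  wk_dense <- 0:5
  wk_sparse <- 10:15
  weeks <- c(rep(list(c(wk_dense, 8)), 10), rep(list(wk_sparse), 2))
  g <- gen_season_dataset(season_gen_config(
    n_participants = 12, weeks = weeks, trend_shape = "flat", beta0 = 60,
    sd_b0 = 2, sd_b1 = 0.1, sd_eps = 2, seed = 9))
  f <- fit_model(g$data, design_spec("nonlinear"))
  cv <- predict_curve(f, c(3, 13))
  hw <- (cv$hi95 - cv$lo95) / 2
  expect_lt(hw[[1]], hw[[2]])
})

test_that("individual curves add shrunken athlete effects", {
  g <- season_fixture(seed = 3)
  f <- fit_model(g$data, design_spec("nonlinear"))
  cv <- predict_curve(f, 0:27, level = "individual")
  ind <- attr(cv, "individual")
  expect_equal(dim(ind), c(28, 12))
  expect_equal(unname(ind[, 1] - cv$mean),
               unname(f$b0[[1]] + f$b1[[1]] * (0:27)), tolerance = 1e-9)
})

test_that("extrapolation warns but returns a result", {
  g <- season_fixture(seed = 5)
  f <- fit_model(g$data, design_spec("nonlinear"))
  expect_warning(cv <- predict_curve(f, 0:40), "beyond")
  expect_true(attr(cv, "extrapolated"))
  expect_equal(nrow(cv), 41)
})

test_that("weekly percentage change follows its definition", {
  # constant curve -> all zeros
  const <- data.frame(week = 0:5, mean = rep(70, 6))
  expect_true(all(weekly_percent_change(const)$per_week == 0))
  # geometric growth 1.01^w -> exactly 1% per week
  geo <- data.frame(week = 0:10, mean = 100 * 1.01^(0:10))
  pc <- weekly_percent_change(geo)
  expect_equal(unname(pc$per_week), rep(1, 10), tolerance = 1e-9)
  expect_equal(pc$window_mean, 1, tolerance = 1e-9)
  # worked three-point example
  three <- data.frame(week = 0:2, mean = c(100, 102, 99))
  pc3 <- weekly_percent_change(three)
  expect_equal(unname(pc3$per_week), c(2, -100 * 3 / 102),
               tolerance = 1e-9)
  expect_equal(pc3$window_mean, mean(c(2, -100 * 3 / 102)),
               tolerance = 1e-9)
  # windowing restricts the averaged transitions
  pcw <- weekly_percent_change(geo, window = c(2, 5))
  expect_length(pcw$per_week, 3)
  # error paths
  expect_error(weekly_percent_change(data.frame(week = c(0, 2, 4),
                                                mean = c(1, 2, 3))),
               class = "invalid_parameter")
  expect_error(weekly_percent_change(data.frame(week = 0:2,
                                                mean = c(0, 1, 2))),
               class = "undefined_ratio")
})

test_that("curve CSV export carries the week/mean/CI columns", {
  g <- season_fixture(seed = 6)
  f <- fit_model(g$data, design_spec("nonlinear"))
  cv <- predict_curve(f, 0:27)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  back <- read.csv(path)
  expect_named(back, c("week", "mean", "lo95", "hi95"))
  expect_equal(back$mean, cv$mean, tolerance = 1e-9)
})
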