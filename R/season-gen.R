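#' Configuration for the synthetic season-long cadence generator
#'
#' Generates longitudinal race observations following the additive mixed
#' model used for analysis: for athlete i at week t,
#' `C_it = beta0 + f(W_it) + beta2 * season2_it + b0_i + b1_i * W_it + eps_it`
#' with `b0_i ~ N(0, sd_b0^2)`, `b1_i ~ N(0, sd_b1^2)` and
#' `eps_it ~ N(0, sd_eps^2)`. The population trend `f` is selected by
#' `trend_shape`:
#' * `"flat"` — f = 0;
#' * `"linear"` — f(W) = beta1 * W;
#' * `"u_shape"` — a negative Gaussian dip of depth `trend_amp` centred
#'   mid-season (cadence drops then recovers);
#' * `"rise_plateau"` — a logistic rise of height `trend_amp` saturating in
#'   the second half of the season.
#'
#' @param n_participants Number of athletes (>= 2).
#' @param weeks Observation weeks: either a numeric vector shared by all
#'   athletes or a list of length `n_participants` (each with >= 1 week).
#' @param trend_shape One of `"flat"`, `"linear"`, `"u_shape"`,
#'   `"rise_plateau"`.
#' @param beta0 Baseline cadence (events/min).
#' @param beta1 Linear slope (events/min/week; used by `"linear"`).
#' @param beta2 Season-2 offset (events/min).
#' @param trend_amp Magnitude of the non-linear trend (events/min; used by
#'   `"u_shape"` and `"rise_plateau"`).
#' @param sd_b0,sd_b1,sd_eps SDs of random intercepts, random slopes and
#'   residual noise (all >= 0).
#' @param seasons `1` (all observations in season 1) or `2` (roughly one
#'   third of athletes race both seasons, the remainder split between them,
#'   with weeks restarting at each season).
#' @param discipline Discipline label carried in the dataset.
#' @param seed Integer RNG seed, or `NULL`.
#' @return An object of class `season_gen_config`.
#' @export
season_gen_config <- function(n_participants = 12,
                              weeks = seq(0, 27, by = 3),
                              trend_shape = c("flat", "linear", "u_shape",
                                              "rise_plateau"),
                              beta0 = 60, beta1 = 0.1, beta2 = 1,
                              trend_amp = 3,
                              sd_b0 = 4, sd_b1 = 0.2, sd_eps = 2,
                              seasons = 1,
                              discipline = "swim",
                              seed = NULL) {
  trend_shape <- match.arg(trend_shape)
  if (!is_scalar_num(n_participants) || n_participants < 2) {
    tri_abort("n_participants must be >= 2", "invalid_config")
  }
  n_participants <- as.integer(n_participants)
  check_scalar(sd_b0, "sd_b0", lower = 0)
  check_scalar(sd_b1, "sd_b1", lower = 0)
  check_scalar(sd_eps, "sd_eps", lower = 0)
  if (!seasons %in% c(1, 2)) {
    tri_abort("seasons must be 1 or 2", "invalid_config")
  }
  if (is.numeric(weeks)) weeks <- rep(list(sort(weeks)), n_participants)
  if (!is.list(weeks) || length(weeks) != n_participants ||
      any(vapply(weeks, length, 0L) < 1L)) {
    tri_abort(
      "weeks must be a numeric vector or a list with >= 1 week per athlete",
      "invalid_config")
  }
  structure(list(n_participants = n_participants, weeks = weeks,
                 trend_shape = trend_shape, beta0 = beta0, beta1 = beta1,
                 beta2 = beta2, trend_amp = trend_amp,
                 sd_b0 = sd_b0, sd_b1 = sd_b1, sd_eps = sd_eps,
                 seasons = seasons, discipline = discipline, seed = seed),
            class = "season_gen_config")
}

# Population trend evaluated at week w; anchored so that f(min week) = 0.
trend_fun <- function(config) {
  wk <- range(unlist(config$weeks))
  mid <- mean(wk)
  span <- max(diff(wk), 1)
  switch(config$trend_shape,
    flat = function(w) rep(0, length(w)),
    linear = function(w) config$beta1 * w,
    u_shape = local({
      s <- span / 6
      a <- config$trend_amp
      f0 <- -a * exp(-(wk[[1L]] - mid)^2 / (2 * s^2))
      function(w) -a * exp(-(w - mid)^2 / (2 * s^2)) - f0
    }),
    rise_plateau = local({
      s <- span / 8
      a <- config$trend_amp
      f0 <- plogis((wk[[1L]] - mid) / s)
      function(w) a * (plogis((w - mid) / s) - f0)
    }))
}

#' Generate a season-long longitudinal cadence dataset
#'
#' Draws random intercepts, random slopes and residuals from the configured
#' model and returns the dataset together with the full generating record
#' (true coefficients, per-athlete random effects, trend values and
#' residuals), so that fitted models can be scored against the truth and the
#' observations can be reconstructed exactly.
#'
#' @param config A [season_gen_config()].
#' @return A list with `data` (a data frame with columns `participant_id`,
#'   `week`, `season`, `discipline`, `cadence`, `distance_m`, `duration_s`,
#'   `flags`) and `truth` (list of generating parameters; `b0`, `b1` are
#'   named per-athlete vectors, `f`, `eps` align with the rows of `data`).
#' @export
gen_season_dataset <- function(config) {
  if (!inherits(config, "season_gen_config")) {
    tri_abort("config must be a season_gen_config", "invalid_config")
  }
  with_seed(config$seed, gen_season_dataset_impl(config))
}

gen_season_dataset_impl <- function(config) {
  np <- config$n_participants
  ids <- sprintf("P%02d", seq_len(np))
  # season membership: with two seasons, the first third race both
  season_of <- function(i) {
    if (config$seasons == 1) return(1L)
    n_both <- max(1L, floor(np / 3))
    if (i <= n_both) c(1L, 2L) else if (i %% 2 == 0) 1L else 2L
  }
  f <- trend_fun(config)
  b0 <- rnorm(np, 0, config$sd_b0)
  b1 <- rnorm(np, 0, config$sd_b1)
  names(b0) <- names(b1) <- ids

  rows <- list()
  for (i in seq_len(np)) {
    for (s in season_of(i)) {
      w <- config$weeks[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids[[i]], week = w, season = s,
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  n <- nrow(d)
  eps <- rnorm(n, 0, config$sd_eps)
  fw <- f(d$week)
  d$cadence <- config$beta0 + fw + config$beta2 * (d$season == 2) +
    b0[d$participant_id] + b1[d$participant_id] * d$week + eps
  d$discipline <- config$discipline
  # plausible race descriptors (sprint-distance legs); not used by the models
  leg <- c(swim = 750, cycle = 20000, run = 5000)[[config$discipline]]
  speed <- c(swim = 1.25, cycle = 9.5, run = 3.6)[[config$discipline]]
  d$distance_m <- leg
  d$duration_s <- round(leg / speed)
  d$flags <- ""
  d <- d[, c("participant_id", "week", "season", "discipline", "cadence",
             "distance_m", "duration_s", "flags")]
  rownames(d) <- NULL
  list(data = d,
       truth = list(beta0 = config$beta0, beta1 = config$beta1,
                    beta2 = config$beta2, trend_shape = config$trend_shape,
                    trend_amp = config$trend_amp, trend = f,
                    sd_b0 = config$sd_b0, sd_b1 = config$sd_b1,
                    sd_eps = config$sd_eps,
                    b0 = b0, b1 = b1, f = fw, eps = eps,
                    seed = config$seed))
}

#' Write / read a longitudinal cadence dataset as CSV
#'
#' Columns: `participant_id, week, season, discipline, cadence, distance_m,
#' duration_s, flags`; `flags` holds semicolon-joined tokens.
#'
#' @param data Data frame in the layout produced by [gen_season_dataset()].
#' @param path File path.
#' @return `write_season_csv` returns `path` invisibly; `read_season_csv`
#'   returns the data frame.
#' @export
write_season_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_season_csv
#' @export
read_season_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$flags <- ifelse(is.na(d$flags), "", as.character(d$flags))
  d
}
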