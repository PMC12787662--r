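#' Pipeline configuration
#'
#' Bundles every sub-configuration of the simulate -> detect -> assemble ->
#' model -> report pipeline. Stage-specific child seeds are derived
#' deterministically from the master seed, so a pipeline run is fully
#' reproducible from `seed`.
#'
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if missing).
#' @param disciplines Subset of `c("swim", "cycle", "run")`.
#' @param season Named list of [season_gen_config()] arguments shared by
#'   the disciplines (participants, weeks, trend, variances ...).
#' @param race_duration_s Length of each simulated race recording (s).
#' @param sample_rate_hz IMU sampling rate (Hz).
#' @param noise_snr_db,jitter_cv,spike_rate_per_min Signal degradation
#'   settings passed to [signal_gen_config()].
#' @param detection Named list of [detection_params()] per discipline
#'   (defaults per discipline).
#' @param k_basis Smooth basis dimension for the non-linear model.
#' @param write_events Write one events CSV per simulated recording
#'   (default TRUE).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir,
                            disciplines = c("swim", "cycle", "run"),
                            season = list(),
                            race_duration_s = 120,
                            sample_rate_hz = 100,
                            noise_snr_db = 10,
                            jitter_cv = 0.05,
                            spike_rate_per_min = 2,
                            detection = NULL,
                            k_basis = 10,
                            write_events = TRUE) {
  disciplines <- match.arg(disciplines, c("swim", "cycle", "run"),
                           several.ok = TRUE)
  check_scalar(seed, "seed")
  check_scalar(race_duration_s, "race_duration_s", lower = 0,
               strict_lower = TRUE)
  detection <- detection %||%
    setNames(lapply(disciplines, default_detection_params), disciplines)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 disciplines = disciplines, season = season,
                 race_duration_s = race_duration_s,
                 sample_rate_hz = sample_rate_hz,
                 noise_snr_db = noise_snr_db, jitter_cv = jitter_cv,
                 spike_rate_per_min = spike_rate_per_min,
                 detection = detection, k_basis = k_basis,
                 write_events = isTRUE(write_events)),
            class = "pipeline_config")
}

# cadence range within which a simulated race observation is physically
# renderable as an event train for detection
clamp_rate <- c(swim = 40, cycle = 120, run = 60,
                swim_hi = 100, cycle_hi = 220, run_hi = 110)

#' Run the full simulate-detect-assemble-model pipeline
#'
#' For each discipline: generates a season-long cadence dataset with known
#' parameters, renders every race observation as a synthetic IMU recording
#' at that cadence, detects the events with the discipline's detector,
#' recomputes the average cadence from the detections, assembles the
#' longitudinal dataset, fits the linear and non-linear season models,
#' compares them, and writes the report bundle (`season.csv`,
#' `curves_<discipline>.csv`, per-recording `events/` CSVs, `report.json`,
#' `pipeline.log`) into the output directory. Outputs are byte-identical
#' under identical seeds.
#'
#' @param config A [pipeline_config()].
#' @return The report list, invisibly.
#' @export
run_end_to_end <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    tri_abort("config must be a pipeline_config", "invalid_config")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logf <- function(stage, fmt, ...) {
    writeLines(sprintf("[%s] %s", stage, sprintf(fmt, ...)), log_con)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      logf(stage, "ERROR: %s", conditionMessage(e))
      stop(errorCondition(
        sprintf("pipeline stage `%s` failed: %s", stage,
                conditionMessage(e)),
        class = c("pipeline_stage_error", class(e))))
    })
  }
  if (config$write_events) {
    dir.create(file.path(config$out_dir, "events"), showWarnings = FALSE)
  }
  report <- list(seed = config$seed, disciplines = list())
  season_all <- list()

  for (d_i in seq_along(config$disciplines)) {
    disc <- config$disciplines[[d_i]]
    seed_sim <- derive_seed(config$seed, 10 * d_i + 1)
    seed_det <- derive_seed(config$seed, 10 * d_i + 2)

    truth_set <- run_stage("simulate", {
      args <- config$season
      args$discipline <- disc
      args$seed <- seed_sim
      gen_season_dataset(do.call(season_gen_config, args))
    })
    d <- truth_set$data
    logf("simulate", "%s: %d observations, %d athletes", disc, nrow(d),
         length(unique(d$participant_id)))

    det <- run_stage("detect", {
      lo <- clamp_rate[[disc]]
      hi <- clamp_rate[[paste0(disc, "_hi")]]
      rates <- pmin(pmax(d$cadence, lo), hi)
      acc <- numeric(nrow(d))
      cad <- numeric(nrow(d))
      for (r in seq_len(nrow(d))) {
        cfg <- signal_gen_config(
          disc, duration_s = config$race_duration_s,
          sample_rate_hz = config$sample_rate_hz,
          cadence = rates[[r]], jitter_cv = config$jitter_cv,
          noise_snr_db = config$noise_snr_db,
          spike_rate_per_min = config$spike_rate_per_min,
          seed = derive_seed(seed_det, r))
        sim <- gen_imu_recording(cfg)
        ev <- detect_events(sim$recording, disc,
                            config$detection[[disc]])
        if (config$write_events) {
          write_events_csv(ev, file.path(
            config$out_dir, "events",
            sprintf("%s_%s_w%02d_s%d.csv", disc, d$participant_id[[r]],
                    d$week[[r]], d$season[[r]])))
        }
        acc[[r]] <- 100 * (1 - abs(ev$count - sim$truth$count) /
                             sim$truth$count)
        cad[[r]] <- average_cadence(ev, config$race_duration_s)
      }
      list(accuracy = acc, cadence = cad)
    })
    logf("detect", "%s: %d recordings, mean count accuracy %.2f%%",
         disc, nrow(d), mean(det$accuracy))

    assembled <- run_stage("assemble", {
      obs <- d
      obs$cadence <- det$cadence
      obs$date <- sprintf("s%d-w%02d", obs$season, obs$week)
      merged <- merge_same_day(obs)
      # disciplines are simulated in isolation, so the triathlon
      # preceding-leg chaining rule does not apply here
      kept <- apply_exclusions(merged, chain_disciplines = FALSE)
      kept$date <- NULL
      kept
    })
    logf("assemble", "%s: %d observations in, %d retained", disc,
         nrow(d), nrow(assembled))
    season_all[[disc]] <- assembled

    model <- run_stage("model", {
      fit_lin <- fit_model(assembled, design_spec("linear"))
      fit_nl <- fit_model(assembled,
                          design_spec("nonlinear",
                                      k_basis = config$k_basis))
      cmp <- compare_models(fit_lin, fit_nl)
      grid <- seq(floor(min(assembled$week)), ceiling(max(assembled$week)))
      curve <- predict_curve(fit_nl, grid)
      write_curve_csv(curve, file.path(
        config$out_dir, sprintf("curves_%s.csv", disc)))
      pct <- weekly_percent_change(curve)
      norm <- ks_normality(assembled$cadence,
                           seed = derive_seed(config$seed, 99))
      list(fit_lin = fit_lin, fit_nl = fit_nl, cmp = cmp, curve = curve,
           pct = pct, norm = norm)
    })
    logf("model", "%s: D = %.3f (p = %.4g), eDF smooth = %.2f", disc,
         model$cmp$D, model$cmp$p, model$fit_nl$edf_smooth)

    fit_fields <- function(f) {
      out <- list(model_type = f$spec$model_type, beta0 = f$beta0,
                  beta1 = f$beta1, beta2 = f$beta2,
                  var_b0 = f$var_b0, var_b1 = f$var_b1, var_eps = f$var_eps,
                  lambdas = as.list(f$lambdas), edf_smooth = f$edf_smooth,
                  edf_total = f$edf_total, loglik = f$loglik,
                  reml_score = f$reml_score, aic = f$aic, bic = f$bic,
                  r2_adj = f$r2_adj)
      # fields that do not exist for this model type (e.g. beta1 in the
      # smooth model) are dropped rather than reported as NA
      drop <- vapply(out, function(v) is.numeric(v) && length(v) == 1 &&
                       is.na(v), logical(1))
      out[!drop]
    }
    report$disciplines[[disc]] <- list(
      n_obs = nrow(assembled),
      detection_accuracy_pct = mean(det$accuracy),
      ks_normality = model$norm,
      linear = fit_fields(model$fit_lin),
      nonlinear = fit_fields(model$fit_nl),
      comparison = list(D = model$cmp$D, df = model$cmp$df, p = model$cmp$p),
      weekly_pct_change_mean = model$pct$window_mean)
  }

  run_stage("report", {
    season_df <- do.call(rbind, season_all)
    rownames(season_df) <- NULL
    write_season_csv(season_df, file.path(config$out_dir, "season.csv"))
    vals <- rapply(report, identity, classes = c("numeric", "integer"),
                   how = "unlist")
    if (!all(is.finite(vals))) {
      tri_abort("non-finite value in report", "invalid_config")
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  logf("report", "wrote report.json (seed %d)", config$seed)
  invisible(report)
}
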