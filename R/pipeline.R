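# End-to-end orchestration: simulate a recording campaign (videos, thermal
# stacks, weather, milk records), extract all features, train the network
# with neuron trimming, evaluate development and deployment accuracy, and
# write every artifact of the run to a directory.

#' Pipeline configuration
#'
#' Defaults reproduce the emulated study conditions: 150 development and 132
#' deployment recordings, one-minute 30-fps RGB videos, 5-fps thermal
#' stacks, a winter weather profile, neuron trimming over 3/5/7/10 hidden
#' units and a 70/30 split.  Tests and examples pass reduced sizes through
#' the same fields.
#'
#' @param n_dev,n_deploy development / deployment recording counts.
#' @param seed master seed; every stage's randomness derives from it.
#' @param out_dir run output directory.
#' @param scene list of scene overrides (`duration_s`, `fps`, `frame_size`,
#'   `noise_sd`, `pulse_amplitude`, `resp_amplitude`).
#' @param thermal list of thermal overrides (`fps`, `frame_size`,
#'   `noise_sd`, `background_c`).
#' @param hr_band,rr_band analysis pass bands, Hz.
#' @param sizes neuron-trimming candidate hidden sizes.
#' @param train_frac training fraction of the development set.
#' @param max_epochs training epoch budget.
#' @param oracle_r calibration of the milk-target noise (see
#'   [gen_herd_dataset()]).
#' @param weather a [weather_profile()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_dev = 150, n_deploy = 132, seed = 1L,
                            out_dir = file.path(tempdir(), "bovitals_run"),
                            scene = list(), thermal = list(),
                            hr_band = c(0.67, 2.5), rr_band = c(0.15, 1.2),
                            sizes = c(3, 5, 7, 10), train_frac = 0.7,
                            max_epochs = 300L, oracle_r = 0.96,
                            weather = weather_profile()) {
  scene_def <- list(duration_s = 60, fps = 30, frame_size = c(360, 640),
                    noise_sd = 1, pulse_amplitude = 2, resp_amplitude = 3)
  thermal_def <- list(fps = 5, frame_size = c(120, 160), noise_sd = 0.2,
                      background_c = 12)
  scene_def[names(scene)] <- scene
  thermal_def[names(thermal)] <- thermal
  cfg <- list(n_dev = n_dev, n_deploy = n_deploy, seed = as.integer(seed),
              out_dir = out_dir, scene = scene_def, thermal = thermal_def,
              hr_band = hr_band, rr_band = rr_band, sizes = sizes,
              train_frac = train_frac, max_epochs = max_epochs,
              oracle_r = oracle_r, weather = weather)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (cfg$n_dev < 2 || cfg$n_deploy < 1) {
    stop("config: need n_dev >= 2 and n_deploy >= 1", call. = FALSE)
  }
  if (!(cfg$train_frac > 0 && cfg$train_frac < 1)) {
    stop("config: train_frac must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$hr_band[1L] <= 0 || cfg$hr_band[2L] >= cfg$scene$fps / 2 ||
      cfg$rr_band[1L] <= 0 || cfg$rr_band[2L] >= cfg$scene$fps / 2) {
    stop("config: analysis bands must lie inside (0, fps/2)", call. = FALSE)
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unspecified keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, y)
}

run_stage <- function(name, log_con, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    msg <- sprintf("stage %s failed: %s", name, conditionMessage(e))
    try(writeLines(msg, log_con), silent = TRUE)
    stop(msg, call. = FALSE)
  })
  writeLines(sprintf("[%s] stage %s done in %.1f s", format(Sys.time()),
                     name, as.numeric(difftime(Sys.time(), t0, "secs"))),
             log_con)
  res
}

#' Run the full synthetic pipeline
#'
#' Simulates `n_dev + n_deploy` cow recordings (RGB video, thermal stack,
#' weather match, milk records), extracts heart rate, respiration rate,
#' movement metrics and eye temperature, assembles the 37-column feature
#' table, trains the Bayesian-regularized network with neuron trimming on
#' the development set, evaluates development and deployment accuracy, and
#' writes `features.csv`, `targets.csv`, `model.json`,
#' `development_report.csv`, `deployment_report.csv`, `summary_by_age.csv`
#' and `run.log` into `out_dir`.  Reruns with the same seed reproduce the
#' feature table byte for byte.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return invisibly, a list with the run directory, the selected model,
#'   the trimming trials and both regression reports.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)

  n <- config$n_dev + config$n_deploy
  ids <- sprintf("cow_%04d", seq_len(n))

  sim <- run_stage("simulate", log_con, {
    with_seed(config$seed, {
      age_w <- c(42, 46, 63, 19, 38, 10, 14, 24, 23, 3)
      list(
        ages = sample(2:11, n, replace = TRUE, prob = age_w / sum(age_w)),
        hr = pmin(pmax(rnorm(n, 82, 8), 60), 110),
        rr = pmin(pmax(rnorm(n, 34, 6), 20), 60),
        rec_seed = sample.int(.Machine$integer.max - 1L, 2L * n),
        t_rec = as.POSIXct("2021-07-14 09:00:00", tz = "UTC") +
          runif(n, 0, 7 * 3600)
      )
    })
  })

  weather_derived <- run_stage("weather", log_con, {
    series <- gen_weather_series("2021-07-14 09:00:00", "2021-07-14 16:00:00",
                                 profile = config$weather,
                                 seed = config$seed + 1L)
    derived <- derive_weather(series)
    rows <- do.call(rbind, lapply(seq_len(n), function(i) {
      suppressWarnings(match_weather(sim$t_rec[i], derived))
    }))
    cbind(id = ids, rows[, setdiff(names(rows), "timestamp")])
  })

  ex <- run_stage("extract", log_con, {
    vit <- vector("list", n); mov <- vector("list", n); eye <- numeric(n)
    for (i in seq_len(n)) {
      sc <- scene_spec(
        duration_s = config$scene$duration_s, fps = config$scene$fps,
        frame_size = config$scene$frame_size,
        hr_bpm = sim$hr[i], rr_brpm = sim$rr[i],
        pulse_amplitude = config$scene$pulse_amplitude,
        resp_amplitude = config$scene$resp_amplitude,
        noise_sd = config$scene$noise_sd, motion_model = "random_walk",
        seed = sim$rec_seed[i]
      )
      rec <- gen_rgb_sequence(sc)
      hr_est <- estimate_heart_rate(rec$frames, rec$eye,
                                    band_hz = config$hr_band)
      rr_est <- estimate_respiration_rate(rec$frames, rec$nose,
                                          band_hz = config$rr_band)
      vit[[i]] <- data.frame(
        id = ids[i],
        hr_bpm = if (hr_est$defined) hr_est$rate else NA_real_,
        hr_amplitude = hr_est$amplitude,
        rr_brpm = if (rr_est$defined) rr_est$rate else NA_real_,
        rr_amplitude = rr_est$amplitude
      )
      mm <- quartile_movement(centroid_series(rec$head))
      mov[[i]] <- cbind(data.frame(id = ids[i]),
                        as.data.frame(t(movement_features(mm))))
      rm(rec)
    }
    list(vitals = do.call(rbind, vit), movement = do.call(rbind, mov))
  })

  assembled <- run_stage("assemble", log_con, {
    feats <- assemble_features(ex$vitals, ex$movement, weather_derived)
    writeLines(sprintf("assembled %d of %d recordings", nrow(feats), n),
               log_con)
    feats
  })

  targets <- run_stage("targets", log_con, {
    # noise-free targets from the true (injected) biometrics plus the
    # measured movement/weather features; milk targets get calibrated noise,
    # the eye-temperature target is the thermal measurement itself
    truth_feats <- assembled
    idx <- match(assembled$id, ids)
    truth_feats$hr_bpm <- sim$hr[idx]
    truth_feats$rr_brpm <- sim$rr[idx]
    clean <- herd_target_function(truth_feats)
    eye_meas <- vapply(seq_along(idx), function(j) {
      i <- idx[j]
      th <- gen_thermal_sequence(
        duration_s = config$scene$duration_s,
        fps_thermal = config$thermal$fps,
        frame_size = config$thermal$frame_size,
        eye_temp_c = clean[j, "eye_temp_c"],
        background_c = config$thermal$background_c,
        noise_sd = config$thermal$noise_sd, seed = sim$rec_seed[n + i]
      )
      eye_temperature(th$frames, th$head)$mean_max
    }, numeric(1))
    noisy <- with_seed(config$seed + 2L, {
      sds <- apply(clean, 2L, sd) * sqrt(1 / config$oracle_r^2 - 1)
      clean + matrix(rnorm(length(clean)), nrow(clean)) %*% diag(sds)
    })
    noisy[, "eye_temp_c"] <- eye_meas
    data.frame(id = assembled$id, as.data.frame(noisy))
  })

  feats37 <- assembled[, feature_columns()]
  dev_pick <- with_seed(config$seed + 3L,
                        sort(sample.int(nrow(assembled), config$n_dev)))
  dep_pick <- setdiff(seq_len(nrow(assembled)), dev_pick)

  trim <- run_stage("train", log_con, {
    neuron_trimming(feats37[dev_pick, ], targets[dev_pick, target_columns()],
                    sizes = config$sizes, seed = config$seed,
                    train_frac = config$train_frac,
                    max_epochs = config$max_epochs)
  })

  dev_report <- run_stage("development_report", log_con, {
    pred <- predict(trim$model, feats37[dev_pick, ])
    regression_report(targets[dev_pick, target_columns()], pred,
                      scaler = trim$model$target_scaler)
  })
  dep_report <- run_stage("deployment_report", log_con, {
    deploy(trim$model, feats37[dep_pick, ], targets[dep_pick, target_columns()])
  })

  summary_age <- run_stage("summarize", log_con, {
    idx <- match(assembled$id, ids)
    summarize_by_group(
      cbind(age = sim$ages[idx], feats37, targets[, target_columns()]),
      "age")
  })

  run_stage("write", log_con, {
    write.csv(assembled, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    write.csv(targets, file.path(config$out_dir, "targets.csv"),
              row.names = FALSE)
    write_ann_model(trim$model, file.path(config$out_dir, "model.json"))
    report_csv <- function(rep, path) {
      base <- data.frame(R = rep$R, slope_b = rep$slope_b, MSE = rep$MSE,
                         n_points = rep$n_points, n_outliers = rep$n_outliers,
                         outlier_pct = rep$outlier_pct)
      write.csv(cbind(base, stats::setNames(
        as.data.frame(t(rep$per_target$R)),
        paste0("R_", rep$per_target$target))), path, row.names = FALSE)
    }
    report_csv(dev_report, file.path(config$out_dir, "development_report.csv"))
    report_csv(dep_report, file.path(config$out_dir, "deployment_report.csv"))
    write.csv(summary_age, file.path(config$out_dir, "summary_by_age.csv"),
              row.names = FALSE)
    write.csv(trim$trials, file.path(config$out_dir, "trimming_trials.csv"),
              row.names = FALSE)
    NULL
  })

  invisible(list(out_dir = config$out_dir, model = trim$model,
                 trials = trim$trials, development = dev_report,
                 deployment = dep_report, summary_by_age = summary_age))
}
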