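# Synthetic herd dataset: a feature table drawn from farm-plausible ranges
# and five targets generated by documented smooth functions of a few
# features plus Gaussian noise.  The noise-free targets are returned so an
# oracle correlation (noise-free vs noisy) is computable, and the target
# noise can be calibrated to a requested oracle R.

#' Specify a synthetic herd
#'
#' @param n_cows number of cow recordings (>= 2).
#' @param ages optional integer ages in years (2--11); sampled from a
#'   herd-like age distribution when omitted.
#' @param noise_sd_targets per-target Gaussian noise sds (length 5, order of
#'   [target_columns()]).  When `NULL`, sds are calibrated per target so the
#'   oracle correlation between noise-free and noisy targets is `oracle_r`.
#' @param oracle_r target oracle correlation used for calibration
#'   (default 0.96).
#' @param weather a [weather_profile()] list of weather-profile centers/sds.
#' @param seed RNG seed.
#' @return an object of class `herd_spec`.
#' @export
herd_spec <- function(n_cows, ages = NULL, noise_sd_targets = NULL,
                      oracle_r = 0.96, weather = weather_profile(),
                      seed = 1L) {
  if (!is.numeric(n_cows) || n_cows < 2) {
    stop("`n_cows` must be >= 2", call. = FALSE)
  }
  if (!is.null(noise_sd_targets)) {
    if (length(noise_sd_targets) != 5L || any(noise_sd_targets < 0)) {
      stop("`noise_sd_targets` must be 5 non-negative sds", call. = FALSE)
    }
  }
  if (!is.null(ages) && (length(ages) != n_cows || any(ages < 2 | ages > 11))) {
    stop("`ages` must be length n_cows with values in 2..11", call. = FALSE)
  }
  structure(list(n_cows = as.integer(n_cows), ages = ages,
                 noise_sd_targets = noise_sd_targets, oracle_r = oracle_r,
                 weather = weather, seed = seed),
            class = "herd_spec")
}

#' Target-matrix column names
#'
#' @return the five modelled targets: eye temperature (degrees C), milk
#'   yield per day and per milking (kg), milk fat and protein (%).
#' @export
target_columns <- function() {
  c("eye_temp_c", "milk_kg_day", "milk_kg_milking", "fat_pct", "protein_pct")
}

#' Noise-free target functions of the feature table
#'
#' The documented ground-truth mapping used by the herd generator.  Each
#' target is a mildly nonlinear (log1p, product) function of at most four
#' features, so that a small nonlinear network genuinely outperforms a
#' straight line:
#' \itemize{
#'   \item eye_temp_c  = 35 + 0.02 (HR-85) + 0.012 (RR-35) - 0.05 (wind-10)
#'         + 0.0006 (HR-85)(RR-35)
#'   \item milk_kg_day = 24 + 0.15 (THI9-43) - 0.8 log1p(var_y)
#'   \item milk_kg_milking = 14 + 0.08 (THI9-43) - 0.5 log1p(var_y)
#'         + 0.02 (HR-85)
#'   \item fat_pct     = 4.1 + 0.012 (RR-35) - 0.10 log1p(var_x)
#'   \item protein_pct = 3.65 + 0.004 (HR-85) + 0.03 (Twet-10)
#'         - 0.05 log1p(var_y)
#' }
#'
#' @param features data.frame containing the [feature_columns()].
#' @return numeric matrix, one column per target.
#' @export
herd_target_function <- function(features) {
  hr <- features$hr_bpm; rr <- features$rr_brpm
  out <- cbind(
    eye_temp_c = 35 + 0.02 * (hr - 85) + 0.012 * (rr - 35) -
      0.05 * (features$wind_speed - 10) + 6e-4 * (hr - 85) * (rr - 35),
    milk_kg_day = 24 + 0.15 * (features$THI9 - 43) -
      0.8 * log1p(features$var_y),
    milk_kg_milking = 14 + 0.08 * (features$THI9 - 43) -
      0.5 * log1p(features$var_y) + 0.02 * (hr - 85),
    fat_pct = 4.1 + 0.012 * (rr - 35) - 0.10 * log1p(features$var_x),
    protein_pct = 3.65 + 0.004 * (hr - 85) + 0.03 * (features$Twet - 10) -
      0.05 * log1p(features$var_y)
  )
  out
}

#' Generate a synthetic herd dataset with known target functions
#'
#' Draws per-recording biometrics (HR 60--110 BPM, RR 20--60 BrPM),
#' log-normal movement variances and quartile centroid statistics, matches
#' each recording to a generated 15-min weather series (with full
#' psychrometric/THI derivation), and produces the five targets via
#' [herd_target_function()] plus Gaussian noise.
#'
#' @param spec a [herd_spec()].
#' @return list with `features` (n x 37 data.frame), `targets` (noisy,
#'   n x 5 data.frame), `targets_noisefree`, `meta` (cow id, age,
#'   timestamp), `noise_sd` (the per-target sds used) and `oracle_r_empirical`
#'   (correlation of noise-free vs noisy targets, per target).
#' @export
gen_herd_dataset <- function(spec) {
  stopifnot(inherits(spec, "herd_spec"))
  n <- spec$n_cows
  with_seed(spec$seed, {
    ages <- spec$ages
    if (is.null(ages)) {
      age_w <- c(42, 46, 63, 19, 38, 10, 14, 24, 23, 3)  # herd-like pyramid
      ages <- sample(2:11, n, replace = TRUE, prob = age_w / sum(age_w))
    }
    hr <- pmin(pmax(rnorm(n, 82, 8), 60), 110)
    rr <- pmin(pmax(rnorm(n, 34, 6), 20), 60)
    hr_amp <- exp(rnorm(n, log(3), 0.3))
    rr_amp <- exp(rnorm(n, log(2), 0.3))

    mx <- rnorm(n, 320, 25); my <- rnorm(n, 180, 20)
    var_x <- exp(rnorm(n, log(30), 0.6)); var_y <- exp(rnorm(n, log(30), 0.6))
    mov <- data.frame(matrix(NA_real_, n, 0))
    for (k in 1:4) mov[[paste0("q_mean_x_", k)]] <- mx + rnorm(n, 0, 4)
    for (k in 1:4) mov[[paste0("q_mean_y_", k)]] <- my + rnorm(n, 0, 4)
    for (k in 1:4) mov[[paste0("q_var_x_", k)]] <- var_x * exp(rnorm(n, 0, 0.3))
    for (k in 1:4) mov[[paste0("q_var_y_", k)]] <- var_y * exp(rnorm(n, 0, 0.3))
    mov$var_x <- var_x; mov$var_y <- var_y

    day0 <- as.POSIXct("2021-07-14 09:00:00", tz = "UTC")
    series <- gen_weather_series(day0, day0 + 7 * 3600,
                                 profile = spec$weather,
                                 seed = spec$seed + 1L)
    derived <- derive_weather(series)
    rec_time <- day0 + runif(n, 0, 7 * 3600)
    widx <- vapply(rec_time, function(tt) {
      d <- abs(as.numeric(derived$timestamp) - as.numeric(tt))
      which(d == min(d))[1L]
    }, integer(1))
    wx <- derived[widx, setdiff(names(derived), "timestamp"), drop = FALSE]

    features <- cbind(
      data.frame(hr_bpm = hr, hr_amplitude = hr_amp,
                 rr_brpm = rr, rr_amplitude = rr_amp),
      mov, wx
    )[, feature_columns()]
    rownames(features) <- NULL

    clean <- herd_target_function(features)
    noise_sd <- spec$noise_sd_targets
    if (is.null(noise_sd)) {
      # sd such that cor(clean, clean + noise) = oracle_r in expectation
      noise_sd <- apply(clean, 2L, sd) * sqrt(1 / spec$oracle_r^2 - 1)
    }
    noisy <- clean + matrix(rnorm(n * 5L), n, 5L) %*% diag(noise_sd)
    colnames(noisy) <- colnames(clean) <- target_columns()
    # percentages stay physical
    noisy[, "fat_pct"] <- pmin(pmax(noisy[, "fat_pct"], 0), 100)
    noisy[, "protein_pct"] <- pmin(pmax(noisy[, "protein_pct"], 0), 100)

    list(
      features = features,
      targets = as.data.frame(noisy),
      targets_noisefree = as.data.frame(clean),
      meta = data.frame(id = sprintf("cow_%04d", seq_len(n)), age = ages,
                        timestamp = rec_time),
      noise_sd = noise_sd,
      oracle_r_empirical = vapply(seq_len(5L), function(j) {
        cor(clean[, j], noisy[, j])
      }, numeric(1))
    )
  })
}
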