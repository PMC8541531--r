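# Synthetic 15-min-cadence weather series emulating a farm station logger in
# a southern-hemisphere winter (cool air, high humidity, moderate wind).

#' Default winter weather profile
#'
#' Centers match the conditions of the emulated recording campaign
#' (T about 11.3 C, RH about 81 %, wind about 11.8 km/h).
#'
#' @param T_mean,T_sd air temperature center/sd, degrees C.
#' @param RH_mean,RH_sd relative humidity center/sd, percent.
#' @param wind_mean,wind_sd wind speed center/sd, km/h.
#' @param dir_mean,dir_sd wind direction center/sd, degrees.
#' @param pressure_mean,pressure_sd surface pressure center/sd, hPa.
#' @return a named list usable as the `profile` of [gen_weather_series()].
#' @export
weather_profile <- function(T_mean = 11.3, T_sd = 1.0,
                            RH_mean = 81.0, RH_sd = 4.0,
                            wind_mean = 11.8, wind_sd = 3.0,
                            dir_mean = 234, dir_sd = 30,
                            pressure_mean = 1013.25, pressure_sd = 2.0) {
  list(T_mean = T_mean, T_sd = T_sd, RH_mean = RH_mean, RH_sd = RH_sd,
       wind_mean = wind_mean, wind_sd = wind_sd,
       dir_mean = dir_mean, dir_sd = dir_sd,
       pressure_mean = pressure_mean, pressure_sd = pressure_sd)
}

#' Generate a synthetic weather series
#'
#' Produces a fixed-cadence logger series with a smooth diurnal temperature
#' component plus Gaussian fluctuation.  Relative humidity is clipped to
#' (0, 100], wind direction wrapped to [0, 360).
#'
#' @param start,end `POSIXct` (or coercible) window bounds, `start < end`.
#' @param cadence_min logging cadence in minutes (default 15).
#' @param profile a [weather_profile()].
#' @param seed RNG seed.
#' @return data.frame with columns `timestamp, T, RH, wind_speed, wind_dir,
#'   pressure`.
#' @export
gen_weather_series <- function(start, end, cadence_min = 15,
                               profile = weather_profile(), seed = 1L) {
  start <- as.POSIXct(start, tz = "UTC"); end <- as.POSIXct(end, tz = "UTC")
  if (!(start < end)) stop("`start` must precede `end`", call. = FALSE)
  stop_if_not_scalar_pos(cadence_min, "cadence_min")
  ts <- seq(start, end, by = cadence_min * 60)
  n <- length(ts)
  with_seed(seed, {
    hour <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
    diurnal <- sin(2 * pi * (hour - 9) / 24)   # afternoon peak
    T <- profile$T_mean + 0.6 * profile$T_sd * diurnal +
      rnorm(n, 0, 0.5 * profile$T_sd)
    RH <- profile$RH_mean - 3 * diurnal + rnorm(n, 0, profile$RH_sd)
    RH <- pmin(pmax(RH, 1), 100)
    wind <- pmax(rnorm(n, profile$wind_mean, profile$wind_sd), 0)
    dir <- (rnorm(n, profile$dir_mean, profile$dir_sd)) %% 360
    pres <- rnorm(n, profile$pressure_mean, profile$pressure_sd)
    data.frame(timestamp = ts, T = T, RH = RH, wind_speed = wind,
               wind_dir = dir, pressure = pres)
  })
}
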