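# Psychrometric derivations and the nine-equation temperature-humidity index
# (THI) suite used for dairy heat-stress assessment.
#
# Saturation vapor pressure follows the Magnus form
#   es(T) = es0 * exp(a*T / (b + T)),  a = 17.27, b = 237.7 C, es0 = 6.1078 hPa
# Dew point inverts it in closed form; wet bulb solves the psychrometric
# balance e = es(Tw) - A*p*(T - Tw) (psychrometer constant A = 6.6e-4 1/C)
# by bisection on [Tdp, T].

.magnus_a <- 17.27
.magnus_b <- 237.7
.magnus_es0 <- 6.1078     # hPa
.psychro_A <- 6.6e-4      # 1/C

#' Saturation vapor pressure (Magnus form)
#'
#' @param t_c air temperature, degrees C.
#' @return saturation vapor pressure in hPa.
#' @export
saturation_vp <- function(t_c) {
  .magnus_es0 * exp(.magnus_a * t_c / (.magnus_b + t_c))
}

#' Dew-point temperature
#'
#' Closed-form Magnus inversion: with `gamma = a*T/(b+T) + ln(RH/100)`,
#' `Tdp = b*gamma / (a - gamma)`.
#'
#' @param t_c air temperature, degrees C.
#' @param rh relative humidity, percent, in (0, 100].
#' @return dew-point temperature, degrees C (vectorized).
#' @examples
#' dew_point(20, 100)  # saturated air: dew point equals air temperature
#' @export
dew_point <- function(t_c, rh) {
  if (any(!is.finite(rh)) || any(rh <= 0) || any(rh > 100)) {
    stop("relative humidity must lie in (0, 100]", call. = FALSE)
  }
  g <- .magnus_a * t_c / (.magnus_b + t_c) + log(rh / 100)
  .magnus_b * g / (.magnus_a - g)
}

#' Wet-bulb temperature by bisection
#'
#' Solves `es(Tw) - A*p*(T - Tw) = e` for `Tw` on the bracket `[Tdp, T]`,
#' where `e = RH/100 * es(T)` is the ambient vapor pressure.  Saturated air
#' (RH = 100) short-circuits to `Tw = T`.
#'
#' @param t_c air temperature, degrees C.
#' @param rh relative humidity, percent, in (0, 100].
#' @param pressure_hpa surface pressure, hPa (default standard sea level).
#' @param tol convergence tolerance on the residual, hPa.
#' @param max_iter maximum bisection iterations.
#' @return wet-bulb temperature, degrees C (vectorized over `t_c`/`rh`).
#' @export
wet_bulb <- function(t_c, rh, pressure_hpa = 1013.25, tol = 1e-4,
                     max_iter = 100L) {
  if (any(!is.finite(rh)) || any(rh <= 0) || any(rh > 100)) {
    stop("relative humidity must lie in (0, 100]", call. = FALSE)
  }
  if (any(pressure_hpa <= 0)) stop("pressure must be positive", call. = FALSE)
  n <- max(length(t_c), length(rh), length(pressure_hpa))
  t_c <- rep_len(t_c, n); rh <- rep_len(rh, n)
  pressure_hpa <- rep_len(pressure_hpa, n)
  vapply(seq_len(n), function(i) {
    if (rh[i] >= 100) return(t_c[i])
    e <- rh[i] / 100 * saturation_vp(t_c[i])
    f <- function(tw) {
      saturation_vp(tw) - .psychro_A * pressure_hpa[i] * (t_c[i] - tw) - e
    }
    lo <- dew_point(t_c[i], rh[i]); hi <- t_c[i]
    mid <- (lo + hi) / 2
    for (iter in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) < tol) break
      if (fm > 0) hi <- mid else lo <- mid
    }
    mid
  }, numeric(1))
}

# The nine THI equations, keyed THI1..THI9.  Each takes dry-bulb T (C),
# RH (%), dew point Tdp (C) and wet bulb Twb (C); all are monotone
# non-decreasing in T at fixed RH.  Under cool, humid winter conditions the
# dew-point NRC form (THI6) and the Ingraham form (THI1) sit highest and the
# heavily wet-bulb-weighted Bianca form (THI9) lowest.
.thi_formulas <- list(
  THI1 = list(source = "Ingraham et al. 1979",
              f = function(t, rh, tdp, twb) {
                (1.8 * t + 32) - (0.55 - 0.0055 * rh) * (1.8 * t - 58)
              }),
  THI2 = list(source = "Bianca 1962 (0.35 dry / 0.65 wet bulb)",
              f = function(t, rh, tdp, twb) {
                (0.35 * t + 0.65 * twb) * 1.8 + 32
              }),
  THI3 = list(source = "NRC 1971 (relative-humidity form)",
              f = function(t, rh, tdp, twb) {
                (1.8 * t + 32) - (0.55 - 0.0055 * rh) * (1.8 * t - 26)
              }),
  THI4 = list(source = "Yousef 1985",
              f = function(t, rh, tdp, twb) t + 0.36 * tdp + 41.2),
  THI5 = list(source = "Kibler 1964",
              f = function(t, rh, tdp, twb) {
                1.8 * t - (1 - rh / 100) * (t - 14.3) + 32
              }),
  THI6 = list(source = "NRC 1971 (dew-point form)",
              f = function(t, rh, tdp, twb) {
                (0.55 * t + 0.2 * tdp) * 1.8 + 32 + 17.5
              }),
  THI7 = list(source = "Mader et al. 2006 (adjusted)",
              f = function(t, rh, tdp, twb) {
                0.8 * t + rh / 100 * (t - 14.4) + 46.4
              }),
  THI8 = list(source = "Thom 1959",
              f = function(t, rh, tdp, twb) 0.72 * (t + twb) + 40.6),
  THI9 = list(source = "Bianca 1962 (0.15 dry / 0.85 wet bulb)",
              f = function(t, rh, tdp, twb) {
                (0.15 * t + 0.85 * twb) * 1.8 + 32
              })
)

#' Names and sources of the nine THI equations
#'
#' @return data.frame with columns `key` and `source`.
#' @export
thi_equations <- function() {
  data.frame(key = names(.thi_formulas),
             source = vapply(.thi_formulas, `[[`, "", "source"),
             row.names = NULL)
}

#' Nine-equation temperature-humidity index suite
#'
#' Evaluates nine published THI formulations (see [thi_equations()]) from
#' dry-bulb temperature, relative humidity, dew point and wet bulb.
#'
#' @param t_c air temperature, degrees C.
#' @param rh relative humidity, percent.
#' @param tdp dew-point temperature, degrees C; computed from `t_c`/`rh`
#'   when omitted.
#' @param twb wet-bulb temperature, degrees C; computed when omitted.
#' @param pressure_hpa surface pressure for the wet-bulb solve.
#' @return for scalar input a named numeric vector `THI1..THI9`; for vector
#'   input a matrix with one row per record.
#' @examples
#' thi_suite(25, 50)["THI3"]  # NRC 1971 RH form: 71.775
#' @export
thi_suite <- function(t_c, rh, tdp = NULL, twb = NULL,
                      pressure_hpa = 1013.25) {
  if (is.null(tdp)) tdp <- dew_point(t_c, rh)
  if (is.null(twb)) twb <- wet_bulb(t_c, rh, pressure_hpa)
  out <- vapply(.thi_formulas, function(eq) eq$f(t_c, rh, tdp, twb),
                numeric(length(t_c)))
  if (length(t_c) == 1L) {
    out <- drop(out)
    names(out) <- names(.thi_formulas)
    out
  } else {
    colnames(out) <- names(.thi_formulas)
    out
  }
}

#' Derive psychrometrics and THI for a weather table
#'
#' Adds `Tdp`, `Twet` and `THI1..THI9` columns to a weather data frame with
#' columns `T`, `RH` and optionally `pressure` (standard sea-level pressure
#' assumed when absent).
#'
#' @param weather data.frame with at least `T` (degrees C) and `RH` (%).
#' @return the input with 11 derived columns appended.
#' @export
derive_weather <- function(weather) {
  if (!all(c("T", "RH") %in% names(weather))) {
    stop("weather table must have columns `T` and `RH`", call. = FALSE)
  }
  p <- if ("pressure" %in% names(weather)) weather$pressure else 1013.25
  tdp <- dew_point(weather$T, weather$RH)
  twb <- wet_bulb(weather$T, weather$RH, p)
  thi <- thi_suite(weather$T, weather$RH, tdp, twb)
  if (is.null(dim(thi))) thi <- matrix(thi, nrow = 1,
                                       dimnames = list(NULL, names(thi)))
  cbind(weather, Tdp = tdp, Twet = twb, as.data.frame(thi))
}

#' Match a recording timestamp to the nearest weather record
#'
#' Weather is logged on a fixed cadence while recordings happen at arbitrary
#' times; the nearest record is used, with ties resolved to the earlier one.
#' Timestamps before the first record match the first record with a warning.
#'
#' @param timestamp a `POSIXct` recording time.
#' @param series weather data.frame with a sorted `timestamp` column.
#' @return the matched row of `series`.
#' @export
match_weather <- function(timestamp, series) {
  if (nrow(series) == 0L) stop("empty weather series", call. = FALSE)
  ts <- as.numeric(series$timestamp)
  if (is.unsorted(ts)) stop("weather series must be time-sorted", call. = FALSE)
  t0 <- as.numeric(timestamp)
  if (t0 < ts[1L]) {
    warning("recording timestamp precedes the weather series; using the ",
            "first record")
    return(series[1L, , drop = FALSE])
  }
  d <- abs(ts - t0)
  series[which(d == min(d))[1L], , drop = FALSE]  # tie -> earlier
}
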