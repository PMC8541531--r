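# Abrupt-movement metrics from the head-box centroid series: the one-minute
# recording is split into four contiguous temporal quartiles whose centroid
# means and variances describe movement patterns; whole-video x/y variances
# are the exported movement intensity features.

#' Head centroid series from an ROI track
#'
#' @param track a `roi_track` (typically the head box).
#' @return data.frame `t, x, y` with `x = x_min + width/2`,
#'   `y = y_min + height/2` per frame, in pixels.
#' @export
centroid_series <- function(track) {
  stopifnot(inherits(track, "roi_track"))
  if (nrow(track) == 0L) stop("empty ROI track", call. = FALSE)
  data.frame(t = track$frame,
             x = track$x_min + track$width / 2,
             y = track$y_min + track$height / 2)
}

# population (divide-by-n) variance
pop_var <- function(x) mean((x - mean(x))^2)

#' Quartile movement metrics
#'
#' Splits the centroid series into four contiguous equal-length temporal
#' blocks (remainder frames joining the last block) and reports per-quartile
#' centroid means and population variances plus whole-series population
#' variances, all in pixels / pixels squared.
#'
#' @param series a centroid series from [centroid_series()] (>= 8 frames).
#' @return list with `q_mean_x`, `q_mean_y`, `q_var_x`, `q_var_y` (length-4
#'   vectors) and `var_x`, `var_y` scalars.
#' @export
quartile_movement <- function(series) {
  n <- nrow(series)
  if (is.null(n) || n < 8L) {
    stop("centroid series too short: need >= 8 frames", call. = FALSE)
  }
  qlen <- n %/% 4L
  starts <- (0:3) * qlen + 1L
  ends <- c(starts[2:4] - 1L, n)   # remainder goes to the last block
  q_stat <- function(v, f) {
    vapply(1:4, function(k) f(v[starts[k]:ends[k]]), numeric(1))
  }
  structure(list(
    q_mean_x = q_stat(series$x, mean), q_mean_y = q_stat(series$y, mean),
    q_var_x = q_stat(series$x, pop_var), q_var_y = q_stat(series$y, pop_var),
    var_x = pop_var(series$x), var_y = pop_var(series$y)
  ), class = "movement_metrics")
}

#' Flatten movement metrics to the 18 feature-table columns
#'
#' @param m a `movement_metrics`.
#' @return named numeric vector with the 18 movement feature columns.
#' @export
movement_features <- function(m) {
  stopifnot(inherits(m, "movement_metrics"))
  out <- c(m$q_mean_x, m$q_mean_y, m$q_var_x, m$q_var_y, m$var_x, m$var_y)
  names(out) <- c(paste0("q_mean_x_", 1:4), paste0("q_mean_y_", 1:4),
                  paste0("q_var_x_", 1:4), paste0("q_var_y_", 1:4),
                  "var_x", "var_y")
  out
}
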