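# Remote photoplethysmography from RGB frame sequences.
#
# Heart rate comes from luminosity changes of the green channel averaged
# over the eye region; respiration rate from the CIELab a* (green-to-red)
# component averaged over the nose region.  Both region-mean traces are
# detrended, band-pass filtered, and analyzed by peak counting, which also
# yields the signal amplitude and a regularity-based quality score.

#' Extract a channel-mean trace from a frame sequence
#'
#' Computes, per frame, the mean over the region's pixels of the requested
#' channel: raw green (`green_rgb`) or the CIELab a* opponent component
#' (`a_cielab`, sRGB D65 conversion in float before averaging).
#'
#' @param seq a `frame_sequence`.
#' @param roi a `roi_track` aligned to `seq` (one box per frame).
#' @param channel `"green_rgb"` or `"a_cielab"`.
#' @return a `signal_trace`: list with `values`, `fps`, `channel`.
#' @export
extract_channel_trace <- function(seq, roi,
                                  channel = c("green_rgb", "a_cielab")) {
  channel <- match.arg(channel)
  stopifnot(inherits(seq, "frame_sequence"), inherits(roi, "roi_track"))
  n <- seq$n_frames
  if (nrow(roi) != n) {
    stop("ROI track has ", nrow(roi), " boxes but the sequence has ", n,
         " frames", call. = FALSE)
  }
  h <- seq$frame_size[1L]; w <- seq$frame_size[2L]
  if (any(roi$width <= 0 | roi$height <= 0)) {
    stop("empty ROI box in track", call. = FALSE)
  }
  if (any(roi$x_min < 0 | roi$y_min < 0 |
          roi$x_min + roi$width > w | roi$y_min + roi$height > h)) {
    stop("ROI box outside frame bounds", call. = FALSE)
  }
  vals <- numeric(n)
  for (t in seq_len(n)) {
    b <- roi[t, ]
    px <- seq$frames[box_rows(b), box_cols(b), , t, drop = FALSE]
    if (channel == "green_rgb") {
      vals[t] <- mean(px[, , 2L, 1L])
    } else {
      m <- cbind(as.vector(px[, , 1L, 1L]), as.vector(px[, , 2L, 1L]),
                 as.vector(px[, , 3L, 1L]))
      vals[t] <- mean(srgb_to_lab(m)[, "a"])
    }
  }
  new_signal_trace(vals, seq$fps, channel)
}

#' Construct a signal trace
#'
#' A 1-D sampled channel-mean signal, the substrate of the peak analysis.
#' Useful for feeding externally computed traces into
#' [detrend_and_filter()] / [peak_rate()].
#'
#' @param values numeric samples (finite).
#' @param fps sampling rate, samples per second.
#' @param channel channel label.
#' @return a `signal_trace`.
#' @export
signal_trace <- function(values, fps, channel = "green_rgb") {
  stopifnot(all(is.finite(values)), fps > 0)
  structure(list(values = values, fps = fps, channel = channel),
            class = "signal_trace")
}

new_signal_trace <- signal_trace

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s, %d samples at %.6g fps\n",
              x$channel, length(x$values), x$fps))
  invisible(x)
}

#' Detrend and band-pass filter a signal trace
#'
#' Subtracts a centered moving-average trend (window `1/low` seconds, partial
#' windows at the edges) and applies a zero-phase order-2 Butterworth
#' band-pass in `[low, high]` Hz via forward-backward filtering.
#'
#' @param trace a `signal_trace`.
#' @param band_hz numeric `c(low, high)` pass band, Hz; must satisfy
#'   `0 < low < high < fps/2`.
#' @return a detrended `signal_trace` with mean approximately zero.
#' @export
detrend_and_filter <- function(trace, band_hz) {
  stopifnot(inherits(trace, "signal_trace"))
  low <- band_hz[1L]; high <- band_hz[2L]
  if (!(low > 0 && low < high && high < trace$fps / 2)) {
    stop("band must satisfy 0 < low < high < fps/2 (Nyquist)", call. = FALSE)
  }
  x <- trace$values
  n <- length(x)
  wlen <- max(3L, round(trace$fps / low))
  half <- wlen %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  trend <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  x <- x - trend
  bf <- signal::butter(2, c(low, high) / (trace$fps / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, x))
  new_signal_trace(y - mean(y), trace$fps, trace$channel)
}

# Local maxima with topographic prominence.  Returns indices of maxima and
# their prominences (peak height above the higher of the two flanking
# minima, where each flank extends to the nearest strictly higher sample or
# the trace end).
find_peaks <- function(x) {
  n <- length(x)
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  # include strict-rise plateau starts missed by the sign trick
  idx <- idx[x[idx] > x[idx - 1L]]
  if (length(idx) == 0L) {
    return(list(idx = integer(0), prominence = numeric(0)))
  }
  prom <- vapply(idx, function(i) {
    lmin <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- x[i]
    j <- i + 1L
    while (j <= n && x[j] <= x[i]) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  list(idx = idx, prominence = prom)
}

#' Rate, amplitude and quality from peak analysis
#'
#' Counts local maxima whose topographic prominence exceeds
#' `prominence_frac` times the trace sd, enforcing a minimum peak
#' separation; the rate is `n_peaks / duration * 60`.  Amplitude is the mean
#' peak-to-preceding-trough excursion; quality is the fraction of inter-peak
#' intervals within 25 % of their median.
#'
#' @param trace a detrended `signal_trace`.
#' @param min_separation_s minimum separation between counted peaks, seconds.
#' @param prominence_frac prominence threshold as a fraction of the trace sd.
#' @return a `vitals_result`: list with `rate` (per minute; `NA` with
#'   `defined = FALSE` when fewer than 2 peaks are found), `amplitude`,
#'   `n_peaks`, `quality`, `defined`.
#' @export
peak_rate <- function(trace, min_separation_s, prominence_frac = 0.25) {
  stopifnot(inherits(trace, "signal_trace"))
  stop_if_not_scalar_pos(min_separation_s, "min_separation_s")
  x <- trace$values
  n <- length(x)
  duration <- n / trace$fps
  pk <- find_peaks(x)
  s <- sd(x)
  keep <- if (s > 0) pk$prominence >= prominence_frac * s else rep(FALSE, length(pk$idx))
  idx <- pk$idx[keep]
  # enforce separation: greedily keep the most prominent peaks
  if (length(idx) > 1L) {
    min_gap <- min_separation_s * trace$fps
    ord <- order(pk$prominence[keep], decreasing = TRUE)
    kept <- integer(0)
    for (i in idx[ord]) {
      if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
    }
    idx <- sort(kept)
  }
  if (length(idx) < 2L) {
    return(structure(list(rate = NA_real_, amplitude = NA_real_,
                          n_peaks = length(idx), quality = 0,
                          defined = FALSE), class = "vitals_result"))
  }
  # preceding trough for each peak
  bounds <- c(1L, idx)
  amp <- vapply(seq_along(idx), function(k) {
    x[idx[k]] - min(x[bounds[k]:idx[k]])
  }, numeric(1))
  iv <- diff(idx) / trace$fps
  quality <- mean(abs(iv - median(iv)) <= 0.25 * median(iv))
  structure(list(rate = length(idx) / duration * 60,
                 amplitude = mean(amp), n_peaks = length(idx),
                 quality = quality, defined = TRUE),
            class = "vitals_result")
}

#' @export
print.vitals_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<vitals_result> rate %.2f /min, %d peaks, amplitude %.3f, quality %.2f\n",
                x$rate, x$n_peaks, x$amplitude, x$quality))
  } else {
    cat("<vitals_result> undefined rate (fewer than 2 peaks)\n")
  }
  invisible(x)
}

#' Spectral rate cross-check
#'
#' Independent of peak counting: the dominant-frequency estimate
#' (FFT-magnitude argmax within the band) times 60.  Used as a quality
#' cross-check on the peak-based rate.
#'
#' @param trace a `signal_trace`.
#' @param band_hz frequency band searched, Hz.
#' @return rate per minute.
#' @export
spectral_rate <- function(trace, band_hz) {
  x <- trace$values - mean(trace$values)
  n <- length(x)
  sp <- Mod(fft(x))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1L) * trace$fps / n
  in_band <- freq >= band_hz[1L] & freq <= band_hz[2L]
  freq[in_band][which.max(sp[in_band])] * 60
}

#' Estimate heart rate from the eye region
#'
#' Green-channel region mean, detrended and band-passed to the bovine
#' cardiac band (0.67--2.5 Hz, 40--150 BPM), then peak analysis with a
#' 0.4 s minimum peak separation.
#'
#' @param seq a `frame_sequence`.
#' @param eye_roi the eye `roi_track`.
#' @param band_hz cardiac pass band, Hz.
#' @param min_separation_s minimum inter-beat separation, seconds.
#' @return a `vitals_result` with `rate` in BPM.
#' @export
estimate_heart_rate <- function(seq, eye_roi, band_hz = c(0.67, 2.5),
                                min_separation_s = 0.4) {
  tr <- extract_channel_trace(seq, eye_roi, "green_rgb")
  peak_rate(detrend_and_filter(tr, band_hz), min_separation_s)
}

#' Estimate respiration rate from the nose region
#'
#' CIELab a* region mean, detrended and band-passed to the bovine
#' respiratory band (0.15--1.2 Hz, 9--72 BrPM), then peak analysis with a
#' 0.8 s minimum separation.
#'
#' @param seq a `frame_sequence`.
#' @param nose_roi the nose `roi_track`.
#' @param band_hz respiratory pass band, Hz.
#' @param min_separation_s minimum inter-breath separation, seconds.
#' @return a `vitals_result` with `rate` in BrPM.
#' @export
estimate_respiration_rate <- function(seq, nose_roi, band_hz = c(0.15, 1.2),
                                      min_separation_s = 0.8) {
  tr <- extract_channel_trace(seq, nose_roi, "a_cielab")
  peak_rate(detrend_and_filter(tr, band_hz), min_separation_s)
}
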