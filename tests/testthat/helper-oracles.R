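# Independent oracles and small fixture builders shared across tests.

# Spectral oracle, independent of the package's estimators: dominant FFT
# frequency within a band, in cycles per minute.
fft_rate_oracle <- function(values, fps, band_hz) {
  x <- values - mean(values)
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1L) * fps / n
  keep <- freq >= band_hz[1L] & freq <= band_hz[2L]
  freq[keep][which.max(sp[keep])] * 60
}

# a reduced-size scene for fast unit tests
small_scene <- function(...) {
  args <- list(...)
  defaults <- list(duration_s = 20, fps = 30, frame_size = c(120, 160),
                   hr_bpm = 78, rr_brpm = 30, noise_sd = 1, seed = 1L)
  defaults[names(args)] <- args
  do.call(scene_spec, defaults)
}

# uniform-color frame sequence (h x w), n frames
constant_frames <- function(rgb, n = 10L, h = 72L, w = 96L, fps = 10) {
  a <- array(0L, dim = c(h, w, 3L, n))
  for (c3 in 1:3) a[, , c3, ] <- as.integer(rgb[c3])
  frame_sequence(a, fps)
}

full_box_track <- function(n, h = 72L, w = 96L, region = "eye") {
  roi_track(seq_len(n) - 1L, region, 0L, 0L, w, h)
}

# pooled scaled per-column-centered correlation between two target tables,
# using the min-max ranges of the first -- the oracle-R convention matching
# the package's model-selection statistic
pooled_scaled_cor <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  mn <- apply(a, 2L, min); rg <- apply(a, 2L, max) - mn
  s <- function(x) {
    z <- sweep(sweep(x, 2L, mn, "-"), 2L, rg / 2, "/") - 1
    sweep(z, 2L, colMeans(z))
  }
  stats::cor(as.vector(s(a)), as.vector(s(b)))
}
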