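# rPPG trace extraction, filtering and peak-based rate estimation.

test_that("channel traces average the requested channel over the ROI", {
  seq10 <- constant_frames(c(100, 150, 100), n = 10)
  tr <- extract_channel_trace(seq10, full_box_track(10), "green_rgb")
  expect_equal(tr$values, rep(150, 10))

  gray <- constant_frames(c(128, 128, 128), n = 5)
  a <- extract_channel_trace(gray, full_box_track(5), "a_cielab")
  expect_true(all(abs(a$values) < 0.5))

  # authored sRGB->Lab conversion agrees with the grDevices reference
  set.seed(42)
  px <- matrix(runif(300) * 255, 100, 3)
  expect_lt(max(abs(srgb_to_lab(px) -
                    grDevices::convertColor(px / 255, "sRGB", "Lab"))), 0.5)

  # track/frame mismatch and out-of-bounds boxes are rejected
  expect_error(extract_channel_trace(seq10, full_box_track(7)), "frames")
  bad <- roi_track(0:9, "eye", 90, 0, 20, 20)
  expect_error(extract_channel_trace(seq10, bad), "bounds")
})

test_that("detrending preserves in-band signal and removes trends", {
  fps <- 30
  t_idx <- 0:(60 * fps - 1)
  s <- signal_trace(sin(2 * pi * 1.3 * t_idx / fps), fps)
  y <- detrend_and_filter(s, c(0.67, 2.5))$values
  # amplitude preserved within 10 % away from filter edge transients
  core <- y[(5 * fps):(55 * fps)]
  expect_lt(abs(max(abs(core)) - 1), 0.1)
  expect_lt(abs(mean(y)), 1e-8)

  ramp <- signal_trace(seq(0, 100, length.out = length(t_idx)), fps)
  yr <- detrend_and_filter(ramp, c(0.67, 2.5))$values
  expect_lt(max(abs(yr)), 0.05 * 100)

  dc <- detrend_and_filter(signal_trace(rep(5, 600), fps), c(0.67, 2.5))
  expect_lt(max(abs(dc$values)), 1e-8)

  expect_error(detrend_and_filter(s, c(2.5, 0.67)), "Nyquist")
  expect_error(detrend_and_filter(s, c(1, 20)), "Nyquist")
})

test_that("peak analysis counts rate, amplitude and quality", {
  fps <- 30
  t_idx <- 0:(60 * fps - 1)
  pure <- signal_trace(sin(2 * pi * 1.0 * t_idx / fps), fps)
  vr <- peak_rate(pure, min_separation_s = 0.4)
  expect_equal(vr$rate, 60)
  expect_equal(vr$n_peaks, 60L)
  expect_equal(vr$quality, 1)
  expect_lt(abs(vr$amplitude - 2), 0.1)   # peak minus preceding trough

  half <- peak_rate(signal_trace(sin(2 * pi * 0.5 * t_idx / fps), fps), 0.8)
  expect_equal(half$rate, 30)

  # noisy 1.3 Hz: within 2 BPM of truth and of the spectral oracle
  set.seed(3)
  noisy <- sin(2 * pi * 1.3 * t_idx / fps) + rnorm(length(t_idx), 0, 0.3)
  est <- peak_rate(detrend_and_filter(signal_trace(noisy, fps), c(0.67, 2.5)),
                   0.4)
  expect_lt(abs(est$rate - 78), 2)
  expect_lt(abs(est$rate - fft_rate_oracle(noisy, fps, c(0.67, 2.5))), 2)

  # degenerate trace: flagged undefined, not silently zero
  flat <- peak_rate(signal_trace(rep(1, 600), fps), 0.4)
  expect_false(flat$defined)
  expect_true(is.na(flat$rate))
  expect_equal(flat$quality, 0)
})

test_that("rate estimates are invariant to added constants and linear trends", {
  fps <- 30
  t_idx <- 0:(40 * fps - 1)
  base <- sin(2 * pi * 1.3 * t_idx / fps)
  r0 <- peak_rate(detrend_and_filter(signal_trace(base, fps),
                                     c(0.67, 2.5)), 0.4)$rate
  r1 <- peak_rate(detrend_and_filter(signal_trace(base + 40 + 0.08 * t_idx,
                                                  fps), c(0.67, 2.5)),
                  0.4)$rate
  expect_equal(r0, r1)
})

test_that("heart and respiration rates are recovered from synthetic cows", {
  rec <- gen_rgb_sequence(small_scene(duration_s = 60, hr_bpm = 78,
                                      rr_brpm = 30, seed = 21))
  hr <- estimate_heart_rate(rec$frames, rec$eye)
  expect_true(hr$defined)
  expect_lt(abs(hr$rate - 78), 2)
  expect_gt(hr$quality, 0.8)

  rr <- estimate_respiration_rate(rec$frames, rec$nose)
  expect_true(rr$defined)
  expect_lt(abs(rr$rate - 30), 1)

  # a faster breather, at the top of the plausible herd means
  rec2 <- gen_rgb_sequence(small_scene(duration_s = 60, hr_bpm = 84,
                                       rr_brpm = 40, seed = 22))
  hr2 <- estimate_heart_rate(rec2$frames, rec2$eye)
  expect_lt(abs(hr2$rate - 84), 2)
  rr2 <- estimate_respiration_rate(rec2$frames, rec2$nose)
  expect_lt(abs(rr2$rate - 40), 1)
})
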