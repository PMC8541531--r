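# Synthetic generators: determinism, injected ground truth, physical bounds.

test_that("RGB generator is deterministic and injects the specified signals", {
  sc <- small_scene(duration_s = 3, noise_sd = 0.5, seed = 11)
  a <- gen_rgb_sequence(sc)
  b <- gen_rgb_sequence(sc)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(a$eye, b$eye)

  # noise-free: eye-region green mean equals base + A*sin within quantization
  sc0 <- small_scene(duration_s = 3, noise_sd = 0, pulse_amplitude = 2,
                     hr_bpm = 78)
  rec <- gen_rgb_sequence(sc0)
  tr <- extract_channel_trace(rec$frames, rec$eye, "green_rgb")
  t_idx <- seq_along(tr$values) - 1L
  expected <- rec$truth$eye_green_base +
    2 * sin(2 * pi * (78 / 60) * t_idx / sc0$fps)
  expect_lt(max(abs(tr$values - expected)), 0.5 + 1e-12)

  # static motion: identical head centroid in every frame
  st <- gen_rgb_sequence(small_scene(duration_s = 1, motion_model = "static",
                                     noise_sd = 0))
  cs <- centroid_series(st$head)
  expect_equal(length(unique(cs$x)), 1L)
  expect_equal(length(unique(cs$y)), 1L)

  # linear drift: centroid series equals the generator's ground-truth path
  dr <- gen_rgb_sequence(small_scene(duration_s = 2, noise_sd = 0,
                                     motion_model = "linear_drift"))
  expect_equal(centroid_series(dr$head)$x, dr$truth$centroid$x)
  expect_equal(centroid_series(dr$head)$y, dr$truth$centroid$y)
})

test_that("scene validation rejects Nyquist violations and out-of-band rates", {
  expect_error(scene_spec(fps = 4, hr_bpm = 145), "Nyquist")
  expect_error(scene_spec(hr_bpm = 200), "out of band")
  expect_error(scene_spec(rr_brpm = 100), "out of band")
  expect_error(scene_spec(frame_size = c(30, 40)), "frame_size")
})

test_that("frame and track round-trips through PNG/CSV preserve values", {
  rec <- gen_rgb_sequence(small_scene(duration_s = 0.5, fps = 10,
                                      frame_size = c(72, 96)))
  d <- withr::local_tempdir()
  write_frame_dir(rec$frames, d)
  back <- read_frame_dir(d, fps = 10)
  expect_identical(back$frames, rec$frames$frames)
  expect_equal(back$n_frames, rec$frames$n_frames)

  p <- file.path(d, "eye.csv")
  write_roi_track(rec$eye, p)
  tr <- read_roi_track(p)
  expect_equal(as.data.frame(tr), as.data.frame(rec$eye))
  expect_s3_class(tr, "roi_track")

  writeLines("frame,region,x_min,y_min,width,height\n0,eye,0,0,-5,10",
             file.path(d, "bad.csv"))
  expect_error(read_roi_track(file.path(d, "bad.csv")), "non-positive")
})

test_that("thermal generator has an exact hot-pixel ground truth", {
  th <- gen_thermal_sequence(duration_s = 2, fps_thermal = 3,
                             frame_size = c(120, 160), eye_temp_c = 36.5,
                             background_c = 12, noise_sd = 0, seed = 5)
  expect_equal(dim(th$frames$frames[[1]]), c(120L, 160L))
  et <- eye_temperature(th$frames, th$head)
  expect_true(all(et$per_frame_max == 36.5))

  # determinism through the CSV export
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  a <- gen_thermal_sequence(duration_s = 1, fps_thermal = 3, noise_sd = 0.3,
                            seed = 9, dir = d1)
  b <- gen_thermal_sequence(duration_s = 1, fps_thermal = 3, noise_sd = 0.3,
                            seed = 9, dir = d2)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(readLines(a$paths[1]), readLines(b$paths[1]))

  # round trip: reading the batch export reproduces the stack
  back <- read_radiometric_csv(a$paths, fps = 3)
  expect_equal(back$frames, a$frames$frames)

  expect_error(gen_thermal_sequence(eye_temp_c = 10, background_c = 12),
               "exceed")
  expect_error(gen_thermal_sequence(duration_s = -1), "duration_s")
})

test_that("weather generator respects cadence, profile centers and bounds", {
  ws <- gen_weather_series("2021-07-14 09:00:00", "2021-07-14 16:00:00",
                           cadence_min = 15, seed = 2)
  expect_equal(nrow(ws), 29L)   # 7 h at 15 min
  prof <- weather_profile()
  expect_lt(abs(mean(ws$T) - prof$T_mean), prof$T_sd)
  expect_lt(abs(mean(ws$RH) - prof$RH_mean), prof$RH_sd)
  expect_lt(abs(mean(ws$wind_speed) - prof$wind_mean), prof$wind_sd)
  expect_true(all(ws$RH > 0 & ws$RH <= 100))
  expect_true(all(ws$wind_dir >= 0 & ws$wind_dir < 360))
  expect_identical(ws, gen_weather_series("2021-07-14 09:00:00",
                                          "2021-07-14 16:00:00",
                                          cadence_min = 15, seed = 2))
  expect_error(gen_weather_series("2021-07-15", "2021-07-14"), "precede")
})

test_that("herd generator calibrates oracle R and is reproducible", {
  d0 <- gen_herd_dataset(herd_spec(60, noise_sd_targets = rep(0, 5), seed = 3))
  expect_equal(unname(d0$oracle_r_empirical), rep(1, 5))

  d1 <- gen_herd_dataset(herd_spec(150, seed = 7))
  d2 <- gen_herd_dataset(herd_spec(150, seed = 7))
  expect_identical(d1$features, d2$features)
  expect_identical(d1$targets, d2$targets)

  expect_identical(names(d1$features), feature_columns())
  expect_equal(ncol(d1$features), 37L)
  expect_true(all(abs(d1$oracle_r_empirical - 0.96) < 0.03))
  expect_true(all(d1$targets$fat_pct >= 0 & d1$targets$fat_pct <= 100))
  expect_true(all(d1$targets$protein_pct >= 0 & d1$targets$protein_pct <= 100))
  expect_true(all(d1$features$RH > 0 & d1$features$RH <= 100))
  expect_true(all(d1$features$hr_bpm >= 60 & d1$features$hr_bpm <= 110))
  expect_true(all(d1$features$rr_brpm >= 20 & d1$features$rr_brpm <= 60))
})

test_that("injected frequencies are recoverable by an independent FFT oracle", {
  for (rates in list(c(66, 24), c(78, 30), c(96, 42))) {
    sc <- small_scene(duration_s = 20, noise_sd = 0, hr_bpm = rates[1],
                      rr_brpm = rates[2], seed = rates[1])
    rec <- gen_rgb_sequence(sc)
    bin_bpm <- 60 * sc$fps / (sc$duration_s * sc$fps)
    g <- extract_channel_trace(rec$frames, rec$eye, "green_rgb")
    expect_lt(abs(fft_rate_oracle(g$values, g$fps, c(0.67, 2.5)) - rates[1]),
              bin_bpm + 1e-9)
    a <- extract_channel_trace(rec$frames, rec$nose, "a_cielab")
    expect_lt(abs(fft_rate_oracle(a$values, a$fps, c(0.15, 1.2)) - rates[2]),
              bin_bpm + 1e-9)
  }
})
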