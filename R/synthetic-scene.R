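# Synthetic RGB recording generator.
#
# Emulates a one-minute tripod recording of a restrained cow: an eye region
# whose green channel carries a cardiac-frequency modulation (the rPPG
# substrate), a nose region whose red/green balance carries a respiratory
# modulation, and a head bounding box that may drift.  Signals are injected
# in float before 8-bit quantization; averaging the region mean over several
# hundred pixels makes sub-quantization amplitudes recoverable.

#' Specify a synthetic RGB scene
#'
#' @param duration_s recording length in seconds (default 60, one minute per
#'   cow).
#' @param fps frames per second (default 30).
#' @param frame_size integer `c(height, width)` in pixels; the default
#'   360 x 640 is a scaled stand-in for a 4K sensor.
#' @param hr_bpm true cardiac rate, beats per minute.  Must lie in the
#'   estimable bovine band (40--150 BPM) and below Nyquist.
#' @param rr_brpm true respiratory rate, breaths per minute (9--72 BrPM).
#' @param pulse_amplitude green-channel modulation amplitude, 8-bit units.
#' @param resp_amplitude red/green-balance modulation amplitude, 8-bit units.
#' @param noise_sd per-pixel Gaussian noise standard deviation, 8-bit units.
#' @param motion_model head motion: `"static"`, `"linear_drift"` (constant
#'   velocity `motion_step` px/frame) or `"random_walk"` (Gaussian steps of
#'   sd `motion_step`).
#' @param motion_step numeric: for `linear_drift` a length-2 velocity
#'   `c(vx, vy)` in px/frame; for `random_walk` a scalar step sd.
#' @param seed RNG seed; identical seeds give bit-identical frames.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(duration_s = 60, fps = 30, frame_size = c(360, 640),
                       hr_bpm = 78, rr_brpm = 30,
                       pulse_amplitude = 2, resp_amplitude = 3,
                       noise_sd = 1, motion_model = c("static", "linear_drift",
                                                      "random_walk"),
                       motion_step = NULL, seed = 1L) {
  motion_model <- match.arg(motion_model)
  stop_if_not_scalar_pos(duration_s, "duration_s")
  stop_if_not_scalar_pos(fps, "fps")
  stop_if_not_scalar_pos(hr_bpm, "hr_bpm")
  stop_if_not_scalar_pos(rr_brpm, "rr_brpm")
  if (length(frame_size) != 2L || frame_size[1L] < 72 || frame_size[2L] < 96) {
    stop("`frame_size` must be c(height, width) with height >= 72 and ",
         "width >= 96 px", call. = FALSE)
  }
  if (hr_bpm / 60 >= fps / 2) {
    stop("Nyquist violation: hr_bpm/60 must be below fps/2", call. = FALSE)
  }
  if (rr_brpm / 60 >= fps / 2) {
    stop("Nyquist violation: rr_brpm/60 must be below fps/2", call. = FALSE)
  }
  if (hr_bpm < 40 || hr_bpm > 150) {
    stop("hr_bpm out of band: the estimable bovine cardiac band is 40-150 BPM",
         call. = FALSE)
  }
  if (rr_brpm < 9 || rr_brpm > 72) {
    stop("rr_brpm out of band: the estimable respiratory band is 9-72 BrPM",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(motion_step)) {
    motion_step <- switch(motion_model,
      static = 0,
      linear_drift = c(0.25, 0.1),
      random_walk = 0.6
    )
  }
  structure(list(
    duration_s = duration_s, fps = fps,
    frame_size = as.integer(frame_size),
    hr_bpm = hr_bpm, rr_brpm = rr_brpm,
    pulse_amplitude = pulse_amplitude, resp_amplitude = resp_amplitude,
    noise_sd = noise_sd, motion_model = motion_model,
    motion_step = motion_step, seed = seed
  ), class = "scene_spec")
}

#' Construct a frame sequence
#'
#' @param frames integer array of 8-bit RGB frames, dim `c(h, w, 3, n)`.
#' @param fps frames per second.
#' @return a `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps) {
  d <- dim(frames)
  stopifnot(length(d) == 4L, d[3L] == 3L)
  stop_if_not_scalar_pos(fps, "fps")
  structure(list(frames = frames, fps = fps, n_frames = d[4L],
                 frame_size = d[1:2]), class = "frame_sequence")
}

new_frame_sequence <- frame_sequence

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.6g fps (%.1f s)\n",
              x$n_frames, x$frame_size[1L], x$frame_size[2L], x$fps,
              x$n_frames / x$fps))
  invisible(x)
}

#' Construct an ROI track
#'
#' Per-frame axis-aligned bounding boxes for a named region, in 0-based
#' pixel units with half-open extents.
#'
#' @param frame 0-based frame indices.
#' @param region region label (`"eye"`, `"nose"` or `"head"`).
#' @param x_min,y_min top-left corner, pixels.
#' @param width,height box extent, pixels (> 0).
#' @return a `roi_track` data.frame.
#' @export
roi_track <- function(frame, region, x_min, y_min, width, height) {
  df <- data.frame(frame = as.integer(frame), region = region,
                   x_min = x_min, y_min = y_min,
                   width = width, height = height)
  class(df) <- c("roi_track", "data.frame")
  df
}

new_roi_track <- roi_track

# 1-based pixel index ranges of a 0-based half-open box
box_rows <- function(box) seq.int(box$y_min + 1L, box$y_min + box$height)
box_cols <- function(box) seq.int(box$x_min + 1L, box$x_min + box$width)

# Base colors of the painted scene (R, G, B on 0-255)
.scene_colors <- list(
  background = c(115, 115, 115),
  head = c(125, 95, 75),
  eye = c(90, 80, 70),
  nose = c(135, 100, 90)
)

# Head-box geometry and the fixed eye/nose offsets within it, for a frame of
# height h and width w.  The eye sits top-left and the nose bottom-right of
# the head box, disjoint and fully contained for any admissible frame size;
# region sizes scale with the frame so the eye region keeps >= 400 px at the
# default and reduced (>= 120 px tall) resolutions.
scene_layout <- function(h, w) {
  head_h <- round(h * 0.5); head_w <- round(w * 0.45)
  s <- max(12L, round(min(head_h, head_w) * 0.38))
  eye_off <- c(round(head_w * 0.08), round(head_h * 0.08))
  nose_off <- c(head_w - s - round(head_w * 0.08),
                head_h - s - round(head_h * 0.04))
  list(head = c(head_w, head_h), eye_off = eye_off, nose_off = nose_off,
       s_eye = s, s_nose = s)
}

#' Generate a synthetic RGB frame sequence with known vital signs
#'
#' Renders a schematic cow scene: within a (possibly drifting) head box, the
#' eye region's green channel oscillates at `hr_bpm/60` Hz and the nose
#' region's red-green balance at `rr_brpm/60` Hz, with iid per-pixel Gaussian
#' noise added before 8-bit quantization.
#'
#' @param spec a [scene_spec()].
#' @return a list with components `frames` (a `frame_sequence`), `eye`,
#'   `nose`, `head` (per-frame `roi_track`s), and `truth` (the injected
#'   `hr_bpm`, `rr_brpm`, the exact head-centroid series, and the region base
#'   colors/amplitudes).
#' @export
gen_rgb_sequence <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$frame_size[1L]; w <- spec$frame_size[2L]
  n <- as.integer(round(spec$duration_s * spec$fps))
  lay <- scene_layout(h, w)
  head_w <- lay$head[1L]; head_h <- lay$head[2L]

  with_seed(spec$seed, {
    # head top-left path (float), clamped so the box stays inside the frame
    x0 <- (w - head_w) / 2; y0 <- (h - head_h) / 2
    t_idx <- seq_len(n) - 1L
    path <- switch(spec$motion_model,
      static = cbind(rep(x0, n), rep(y0, n)),
      linear_drift = cbind(x0 + spec$motion_step[1L] * t_idx,
                           y0 + spec$motion_step[2L] * t_idx),
      random_walk = cbind(x0 + cumsum(c(0, rnorm(n - 1L, 0, spec$motion_step))),
                          y0 + cumsum(c(0, rnorm(n - 1L, 0, spec$motion_step))))
    )
    path[, 1L] <- pmin(pmax(path[, 1L], 0), w - head_w)
    path[, 2L] <- pmin(pmax(path[, 2L], 0), h - head_h)
    hx <- as.integer(round(path[, 1L])); hy <- as.integer(round(path[, 2L]))

    pulse <- spec$pulse_amplitude *
      sin(2 * pi * (spec$hr_bpm / 60) * t_idx / spec$fps)
    resp <- spec$resp_amplitude *
      sin(2 * pi * (spec$rr_brpm / 60) * t_idx / spec$fps)

    cols <- .scene_colors
    canvas <- array(0, dim = c(h, w, 3L))
    for (c3 in 1:3) canvas[, , c3] <- cols$background[c3]

    frames <- array(0L, dim = c(h, w, 3L, n))
    npx <- h * w * 3L
    for (t in seq_len(n)) {
      fr <- canvas
      ry <- seq.int(hy[t] + 1L, hy[t] + head_h)
      rx <- seq.int(hx[t] + 1L, hx[t] + head_w)
      for (c3 in 1:3) fr[ry, rx, c3] <- cols$head[c3]
      ey <- seq.int(hy[t] + lay$eye_off[2L] + 1L, length.out = lay$s_eye)
      ex <- seq.int(hx[t] + lay$eye_off[1L] + 1L, length.out = lay$s_eye)
      for (c3 in 1:3) fr[ey, ex, c3] <- cols$eye[c3]
      fr[ey, ex, 2L] <- cols$eye[2L] + pulse[t]
      ny <- seq.int(hy[t] + lay$nose_off[2L] + 1L, length.out = lay$s_nose)
      nx <- seq.int(hx[t] + lay$nose_off[1L] + 1L, length.out = lay$s_nose)
      for (c3 in 1:3) fr[ny, nx, c3] <- cols$nose[c3]
      fr[ny, nx, 1L] <- cols$nose[1L] + resp[t]
      fr[ny, nx, 2L] <- cols$nose[2L] - resp[t]
      if (spec$noise_sd > 0) fr <- fr + rnorm(npx, 0, spec$noise_sd)
      frames[, , , t] <- as.integer(pmin(pmax(round(fr), 0), 255))
    }

    frame0 <- t_idx
    head_track <- new_roi_track(frame0, "head", hx, hy, head_w, head_h)
    eye_track <- new_roi_track(frame0, "eye", hx + lay$eye_off[1L],
                               hy + lay$eye_off[2L], lay$s_eye, lay$s_eye)
    nose_track <- new_roi_track(frame0, "nose", hx + lay$nose_off[1L],
                                hy + lay$nose_off[2L], lay$s_nose, lay$s_nose)
    truth <- list(
      hr_bpm = spec$hr_bpm, rr_brpm = spec$rr_brpm,
      centroid = data.frame(t = frame0, x = hx + head_w / 2,
                            y = hy + head_h / 2),
      eye_green_base = cols$eye[2L], pulse_amplitude = spec$pulse_amplitude,
      resp_amplitude = spec$resp_amplitude
    )
    list(frames = new_frame_sequence(frames, spec$fps),
         eye = eye_track, nose = nose_track, head = head_track,
         truth = truth)
  })
}

#' Write / read a frame sequence as a PNG directory
#'
#' Frames are written as 8-bit RGB PNG files named `frame_<index>.png` with a
#' zero-padded 0-based frame index, the on-disk interchange format for
#' recordings.
#'
#' @param seq a `frame_sequence`.
#' @param dir output directory (created if missing).
#' @return `write_frame_dir` returns the file paths invisibly;
#'   `read_frame_dir` returns a `frame_sequence`.
#' @export
write_frame_dir <- function(seq, dir) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_len(seq$n_frames) - 1L))
  for (t in seq_len(seq$n_frames)) {
    png::writePNG(seq$frames[, , , t] / 255, target = paths[t])
  }
  invisible(paths)
}

#' @param fps frames per second of the stored sequence.
#' @rdname write_frame_dir
#' @export
read_frame_dir <- function(dir, fps) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frame_*.png files in ", dir, call. = FALSE)
  first <- png::readPNG(files[1L])
  d <- dim(first)
  frames <- array(0L, dim = c(d[1L], d[2L], 3L, length(files)))
  for (t in seq_along(files)) {
    fr <- png::readPNG(files[t])
    if (!identical(dim(fr)[1:2], d[1:2])) {
      stop("frame size mismatch in ", files[t], call. = FALSE)
    }
    frames[, , , t] <- as.integer(round(fr[, , 1:3] * 255))
  }
  new_frame_sequence(frames, fps)
}

#' Write / read an ROI track CSV
#'
#' Tracks are stored as CSV with columns `frame, region, x_min, y_min,
#' width, height` (0-based pixel units, half-open boxes), one row per frame.
#'
#' @param track a `roi_track`.
#' @param path CSV file path.
#' @export
write_roi_track <- function(track, path) {
  stopifnot(inherits(track, "roi_track"))
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_track
#' @export
read_roi_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "region", "x_min", "y_min", "width", "height")
  if (!all(need %in% names(df))) {
    stop("ROI track ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$width)) || any(!is.finite(df$height)) ||
      any(df$width <= 0) || any(df$height <= 0)) {
    stop("ROI track ", path, " contains non-positive or missing box sizes",
         call. = FALSE)
  }
  new_roi_track(df$frame, df$region, df$x_min, df$y_min, df$width, df$height)
}
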