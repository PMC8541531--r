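# Synthetic radiometric thermal stacks: one compact hot region (the eye)
# whose peak pixel equals the requested eye temperature, on a cooler
# background, exported as one CSV matrix of degrees C per frame -- the format
# a radiometric batch export produces.

#' Generate a synthetic thermal frame stack with a known eye temperature
#'
#' Each frame holds a single compact Gaussian-profile hot region whose peak
#' pixel equals `eye_temp_c` plus per-pixel noise, inside a static head
#' bounding box.  The thermal cadence is independent of the RGB cadence.
#'
#' @param duration_s stack length in seconds.
#' @param fps_thermal thermal frames per second (default 5).
#' @param frame_size integer `c(height, width)`; the default 120 x 160 is a
#'   scaled stand-in for a 514 x 652 radiometric sensor.
#' @param eye_temp_c true eye temperature, degrees C; must exceed
#'   `background_c`.
#' @param background_c background temperature, degrees C.
#' @param noise_sd per-pixel Gaussian noise sd, degrees C.
#' @param seed RNG seed.
#' @param dir if non-NULL, frames are also written there as
#'   `frame_<index>.csv` matrices.
#' @return list with `frames` (a `thermal_frame_set`), `head` (a
#'   `roi_track`), `paths` (CSV paths or NULL) and `truth`.
#' @export
gen_thermal_sequence <- function(duration_s = 60, fps_thermal = 5,
                                 frame_size = c(120, 160),
                                 eye_temp_c = 36.5, background_c = 12,
                                 noise_sd = 0.2, seed = 1L, dir = NULL) {
  stop_if_not_scalar_pos(duration_s, "duration_s")
  stop_if_not_scalar_pos(fps_thermal, "fps_thermal")
  if (eye_temp_c <= background_c) {
    stop("eye_temp_c must exceed background_c", call. = FALSE)
  }
  n <- as.integer(round(duration_s * fps_thermal))
  if (n <= 0L) stop("non-positive frame count requested", call. = FALSE)
  h <- as.integer(frame_size[1L]); w <- as.integer(frame_size[2L])

  # head box: centered, half the frame; eye blob inside it
  head_h <- round(h / 2); head_w <- round(w / 2)
  hy <- round((h - head_h) / 2); hx <- round((w - head_w) / 2)
  cy <- hy + round(head_h * 0.35); cx <- hx + round(head_w * 0.4)
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  blob <- exp(-(dx^2 + dy^2) / (2 * 3^2))  # sigma = 3 px, peak exactly 1
  base <- background_c + (eye_temp_c - background_c) * blob

  frames <- with_seed(seed, {
    lapply(seq_len(n), function(t) {
      fr <- base
      if (noise_sd > 0) fr <- fr + rnorm(h * w, 0, noise_sd)
      fr
    })
  })
  fs <- new_thermal_frame_set(frames, fps_thermal)
  head_track <- new_roi_track(seq_len(n) - 1L, "head",
                              rep(hx, n), rep(hy, n), head_w, head_h)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, sprintf("frame_%06d.csv", seq_len(n) - 1L))
    for (t in seq_len(n)) {
      utils::write.table(frames[[t]], paths[t], sep = ",",
                         row.names = FALSE, col.names = FALSE)
    }
  }
  list(frames = fs, head = head_track, paths = paths,
       truth = list(eye_temp_c = eye_temp_c, background_c = background_c,
                    eye_center = c(x = cx, y = cy)))
}

new_thermal_frame_set <- function(frames, fps) {
  d1 <- dim(frames[[1L]])
  structure(list(frames = frames, fps = fps, n_frames = length(frames),
                 frame_size = d1), class = "thermal_frame_set")
}

#' @export
print.thermal_frame_set <- function(x, ...) {
  cat(sprintf("<thermal_frame_set> %d frames, %dx%d px, %.6g fps\n",
              x$n_frames, x$frame_size[1L], x$frame_size[2L], x$fps))
  invisible(x)
}
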