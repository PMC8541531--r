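# Radiometric thermal stack analysis: read per-frame CSV matrices of
# degrees C and extract the eye temperature as the per-frame maximum within
# the tracked head region, summarized as the temporal mean of maxima.

#' Read radiometric CSV frames into a thermal stack
#'
#' Each path must parse as a numeric matrix (comma-separated, no header);
#' all frames must share one shape and contain no missing cells.  Parse
#' problems are reported with the offending file and row.
#'
#' @param paths character vector of CSV file paths, in frame order.
#' @param fps thermal frame rate of the stack.
#' @return a `thermal_frame_set`.
#' @export
read_radiometric_csv <- function(paths, fps = 5) {
  if (length(paths) == 0L) stop("no radiometric files given", call. = FALSE)
  frames <- lapply(paths, function(p) {
    lines <- readLines(p)
    rows <- strsplit(lines, ",", fixed = TRUE)
    ncol1 <- length(rows[[1L]])
    for (i in seq_along(rows)) {
      if (length(rows[[i]]) != ncol1) {
        stop("ragged row in ", p, ": row ", i, " has ", length(rows[[i]]),
             " cells, expected ", ncol1, call. = FALSE)
      }
    }
    vals <- suppressWarnings(as.numeric(unlist(rows)))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      row <- (bad - 1L) %/% ncol1 + 1L
      stop("non-numeric or missing cell in ", p, " at row ", row,
           call. = FALSE)
    }
    matrix(vals, nrow = length(rows), ncol = ncol1, byrow = TRUE)
  })
  d1 <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d1)) {
      stop("frame shape mismatch: ", paths[i], " is ",
           paste(dim(frames[[i]]), collapse = "x"), ", expected ",
           paste(d1, collapse = "x"), call. = FALSE)
    }
  }
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1L] < -20 || rng[2L] > 60) {
    warning("thermal values outside the expected -20..60 C band (",
            sprintf("%.1f..%.1f", rng[1L], rng[2L]), ")")
  }
  new_thermal_frame_set(frames, fps)
}

#' Eye temperature from a thermal stack
#'
#' Implements maximum-face-temperature extraction: the per-frame maximum
#' over the tracked region's pixels, summarized as its temporal mean and sd.
#'
#' @param frames a `thermal_frame_set`.
#' @param roi a `roi_track` aligned to the stack (one box per frame, or a
#'   single box recycled over all frames).
#' @return an `eye_temperature`: list with `per_frame_max`, `mean_max`,
#'   `sd_max`, `n_frames`.
#' @export
eye_temperature <- function(frames, roi) {
  stopifnot(inherits(frames, "thermal_frame_set"), inherits(roi, "roi_track"))
  n <- frames$n_frames
  if (nrow(roi) == 1L) roi <- roi[rep(1L, n), ]
  if (nrow(roi) != n) {
    stop("ROI track length does not match the thermal stack", call. = FALSE)
  }
  h <- frames$frame_size[1L]; w <- frames$frame_size[2L]
  if (any(roi$x_min < 0 | roi$y_min < 0 |
          roi$x_min + roi$width > w | roi$y_min + roi$height > h)) {
    stop("ROI box outside thermal frame bounds", call. = FALSE)
  }
  pfm <- vapply(seq_len(n), function(t) {
    b <- roi[t, ]
    max(frames$frames[[t]][box_rows(b), box_cols(b)])
  }, numeric(1))
  structure(list(per_frame_max = pfm, mean_max = mean(pfm),
                 sd_max = sd(pfm), n_frames = n),
            class = "eye_temperature")
}

#' @export
print.eye_temperature <- function(x, ...) {
  cat(sprintf("<eye_temperature> mean of per-frame max: %.2f C (sd %.3f, %d frames)\n",
              x$mean_max, x$sd_max, x$n_frames))
  invisible(x)
}
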