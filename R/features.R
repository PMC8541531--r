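# The modelled feature table: 37 named inputs per cow recording --
# 4 video biometrics, 18 head-movement statistics, 15 weather-derived values.

#' Canonical feature-table column names
#'
#' The 37 model inputs, in documented order: biometrics (`hr_bpm`,
#' `hr_amplitude`, `rr_brpm`, `rr_amplitude`), per-quartile head-centroid
#' means and variances plus whole-video variances, and the weather block
#' (`T`, `RH`, `wind_speed`, `wind_dir`, `Tdp`, `Twet`, `THI1..THI9`).
#'
#' @return character vector of length 37.
#' @export
feature_columns <- function() {
  c("hr_bpm", "hr_amplitude", "rr_brpm", "rr_amplitude",
    paste0("q_mean_x_", 1:4), paste0("q_mean_y_", 1:4),
    paste0("q_var_x_", 1:4), paste0("q_var_y_", 1:4),
    "var_x", "var_y",
    "T", "RH", "wind_speed", "wind_dir", "Tdp", "Twet",
    paste0("THI", 1:9))
}

#' Assemble the 37-column feature table
#'
#' Inner-joins per-recording vitals, movement metrics and weather-derived
#' records on the `id` key and orders columns canonically.  Recordings
#' missing any component are dropped with a message stating how many.
#'
#' @param vitals data.frame with `id`, `hr_bpm`, `hr_amplitude`, `rr_brpm`,
#'   `rr_amplitude`.
#' @param movement data.frame with `id` plus the 18 movement columns.
#' @param weather_derived data.frame with `id` plus the 15 weather columns.
#' @return data.frame keyed by `id` with exactly 37 feature columns.
#' @export
assemble_features <- function(vitals, movement, weather_derived) {
  for (nm in list(list(vitals, "vitals"), list(movement, "movement"),
                  list(weather_derived, "weather_derived"))) {
    if (!"id" %in% names(nm[[1L]])) {
      stop("`", nm[[2L]], "` must have an `id` column", call. = FALSE)
    }
    if (anyDuplicated(nm[[1L]]$id)) {
      stop("duplicate recording ids in `", nm[[2L]], "`", call. = FALSE)
    }
  }
  n_max <- length(unique(c(vitals$id, movement$id, weather_derived$id)))
  out <- merge(vitals, movement, by = "id")
  out <- merge(out, weather_derived, by = "id")
  dropped <- n_max - nrow(out)
  if (dropped > 0L) {
    message(dropped, " recording(s) dropped for missing components")
  }
  cols <- feature_columns()
  missing_cols <- setdiff(cols, names(out))
  if (length(missing_cols) > 0L) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- out[order(out$id), c("id", cols)]
  rownames(out) <- NULL
  if (anyNA(out[cols])) {
    keep <- stats::complete.cases(out[cols])
    message(sum(!keep), " recording(s) dropped for missing values")
    out <- out[keep, , drop = FALSE]
  }
  out
}
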