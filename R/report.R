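# Regression reporting: pooled predicted-vs-observed statistics across all
# five targets (in min-max scaled units, since the targets carry different
# physical units), outlier counting against the 95 % prediction band of the
# pooled least-squares line, deployment evaluation, PCA and grouped
# summaries.

#' Regression report over pooled targets
#'
#' Pools all targets' points after per-column min-max scaling to `[-1, 1]`
#' and reports the Pearson correlation `R`, the slope of the least-squares
#' fit of predicted on observed, the pooled scaled MSE, and the count of
#' points falling outside the 95 % prediction band of that fit.  Per-target
#' R and MSE in original units are attached as `per_target`.
#'
#' @param observed matrix/data.frame of observed targets.
#' @param predicted matrix of predictions, same shape.
#' @param scaler optional min-max scaler (as stored in an `ann_model`);
#'   derived from the observed columns when omitted.
#' @param level prediction-band level (default 0.95).
#' @return a `regression_report`: list with `R`, `slope_b`, `MSE`,
#'   `n_points`, `n_outliers`, `outlier_pct` (one decimal), `per_target`.
#' @export
regression_report <- function(observed, predicted, scaler = NULL,
                              level = 0.95) {
  observed <- as.matrix(observed); predicted <- as.matrix(predicted)
  if (!all(dim(observed) == dim(predicted))) {
    stop("observed and predicted must have identical shape", call. = FALSE)
  }
  if (nrow(observed) == 0L) stop("no data points", call. = FALSE)
  if (is.null(scaler)) scaler <- make_scaler(observed)
  obs_s <- scale_minmax(observed, scaler)
  pred_s <- scale_minmax(predicted, scaler)
  x <- as.vector(obs_s); y <- as.vector(pred_s)
  n <- length(x)

  mse_scaled <- mean((y - x)^2)
  R <- if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_

  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  slope <- unname(stats::coef(fit)[2L])
  band <- suppressWarnings(
    predict(fit, newdata = data.frame(x = x), interval = "prediction",
            level = level)
  )
  out_mask <- y < band[, "lwr"] | y > band[, "upr"]
  n_out <- sum(out_mask)

  per_target <- data.frame(
    target = colnames(observed) %||% paste0("y", seq_len(ncol(observed))),
    R = vapply(seq_len(ncol(observed)), function(j) {
      if (sd(observed[, j]) > 0 && sd(predicted[, j]) > 0)
        cor(observed[, j], predicted[, j]) else NA_real_
    }, numeric(1)),
    mse = vapply(seq_len(ncol(observed)), function(j) {
      mean((observed[, j] - predicted[, j])^2)
    }, numeric(1))
  )
  structure(list(R = R, slope_b = slope, MSE = mse_scaled, n_points = n,
                 n_outliers = n_out,
                 outlier_pct = round(100 * n_out / n, 1),
                 per_target = per_target),
            class = "regression_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<regression_report> %d points: R = %.3f, slope b = %.3f, ",
    "scaled MSE = %.4g\n  outliers beyond the 95%% prediction band: ",
    "%d (%.1f%%)\n"),
    x$n_points, x$R, x$slope_b, x$MSE, x$n_outliers, x$outlier_pct))
  invisible(x)
}

#' Deployment evaluation on held-out recordings
#'
#' Runs the frozen model forward on an independent feature table and reports
#' the pooled regression statistics against the observed targets (scaled
#' with the model's own target scaler, so development and deployment are on
#' one scale).
#'
#' @param model an `ann_model`.
#' @param X_new held-out feature table.
#' @param Y_new held-out observed targets.
#' @return a `regression_report`; `n_points` equals `nrow(X_new)` times the
#'   number of targets.
#' @export
deploy <- function(model, X_new, Y_new) {
  if (is.null(dim(X_new)) || nrow(as.data.frame(X_new)) == 0L) {
    stop("empty deployment input", call. = FALSE)
  }
  pred <- predict(model, X_new)
  regression_report(as.matrix(Y_new), pred, scaler = model$target_scaler)
}

#' Principal-component summary with factor loadings
#'
#' Z-score standardizes the columns and eigen-decomposes the correlation
#' structure.  Loadings are signed so each component's largest-magnitude
#' element is positive.
#'
#' @param X numeric matrix or data.frame.
#' @return list with `explained_pct` (percent variance per component) and
#'   `loadings` (variables x components).
#' @export
pca_summary <- function(X) {
  X <- as.matrix(X)
  keep <- apply(X, 2L, sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance column(s) dropped before PCA")
    X <- X[, keep, drop = FALSE]
  }
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  expl <- 100 * p$sdev^2 / sum(p$sdev^2)
  load <- p$rotation
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  list(explained_pct = expl, loadings = load)
}

#' Mean and standard error grouped by a key
#'
#' @param records data.frame of per-recording values.
#' @param group_key grouping column name (default `"age"`).
#' @return data.frame with one row per group and variable: `group`,
#'   `variable`, `n`, `mean`, `se` (SE is `NA` for single-member groups).
#' @export
summarize_by_group <- function(records, group_key = "age") {
  if (!group_key %in% names(records)) {
    stop("grouping column `", group_key, "` not found", call. = FALSE)
  }
  vars <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                  group_key)
  groups <- sort(unique(records[[group_key]]))
  rows <- list()
  for (g in groups) {
    sub <- records[records[[group_key]] == g, , drop = FALSE]
    for (v in vars) {
      x <- sub[[v]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, n = length(x), mean = mean(x),
        se = if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
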