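# Forward pass, printing and JSON serialization of the trained network.

#' Predict from a trained network
#'
#' Scales new inputs with the model's stored min-max maps, runs the forward
#' pass `W2 %*% tanh(W1 x + b1) + b2` and unscales the outputs back to
#' original target units.
#'
#' @param object an `ann_model`.
#' @param newdata inputs (data.frame or matrix) with the training columns.
#' @param ... unused.
#' @return numeric matrix of predictions, one column per target, in original
#'   units.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, colnames(newdata) %in% object$input_names,
                         drop = FALSE])
  if (!is.null(object$input_names) && ncol(X) == length(object$input_names)) {
    X <- X[, object$input_names, drop = FALSE]
  } else if (ncol(as.matrix(newdata)) == length(object$input_scaler$min)) {
    X <- as.matrix(newdata)
  } else {
    stop("newdata does not match the model's input columns", call. = FALSE)
  }
  if (nrow(X) == 0L) stop("no rows to predict", call. = FALSE)
  Xs <- scale_minmax(X, object$input_scaler)
  O <- ann_forward_scaled(object[c("W1", "b1", "W2", "b2")], Xs)$O
  out <- unscale_minmax(O, object$target_scaler)
  colnames(out) <- object$target_names
  out
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<ann_model> %d inputs -> %d tanh hidden -> %d linear outputs (%d params)\n",
    "  alpha %.4g, beta %.4g, effective params %.1f, stopped on %s after %d epochs\n"),
    ncol(x$W1), x$hidden_size, nrow(x$W2), x$n_params,
    x$alpha, x$beta, x$gamma_eff, x$stop_reason,
    if (is.null(x$training_log)) 0L else max(x$training_log$epoch)))
  invisible(x)
}

#' Serialize / deserialize a trained network as JSON
#'
#' The on-disk model is a documented JSON object holding weights, biases,
#' per-column min-max scalers, hyperparameters and column names.
#'
#' @param model an `ann_model`.
#' @param path JSON file path.
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  obj <- list(
    hidden_size = model$hidden_size,
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    input_scaler = model$input_scaler, target_scaler = model$target_scaler,
    input_names = model$input_names, target_names = model$target_names,
    alpha = model$alpha, beta = model$beta, gamma_eff = model$gamma_eff,
    n_params = model$n_params, stop_reason = model$stop_reason
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nrow_hint) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = nrow_hint, byrow = TRUE)
  }
  obj$W1 <- as_mat(obj$W1, obj$hidden_size)
  obj$W2 <- as_mat(obj$W2, length(obj$b2))
  obj$input_scaler <- lapply(obj$input_scaler, unlist)
  obj$target_scaler <- lapply(obj$target_scaler, unlist)
  obj$training_log <- NULL
  structure(obj, class = "ann_model")
}
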