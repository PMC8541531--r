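# Model-development protocol: random 70/30 split, the input-count overfit
# guard, and the neuron trimming test over candidate hidden sizes.

#' Random train/test split
#'
#' @param n number of samples (>= 2).
#' @param train_frac training fraction in (0, 1); the training size is
#'   `round(n * train_frac)`, the remainder tests.
#' @param seed RNG seed; identical seeds give identical splits.
#' @return list with disjoint `train` and `test` index vectors whose union
#'   is `1:n`.
#' @examples
#' lengths(split_samples(150, 0.7, seed = 1))  # 105 / 45
#' @export
split_samples <- function(n, train_frac = 0.7, seed = 1L) {
  if (!is.numeric(n) || n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (!(train_frac > 0 && train_frac < 1)) {
    stop("`train_frac` must lie in (0, 1)", call. = FALSE)
  }
  n_train <- round(n * train_frac)
  with_seed(seed, {
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Overfitting guard on the input count
#'
#' A model is admissible only if the number of inputs is below 70 % of the
#' number of training samples.
#'
#' @param n_inputs number of input columns.
#' @param n_train number of training samples.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @examples
#' overfit_guard(37, 105)  # TRUE
#' @export
overfit_guard <- function(n_inputs, n_train) {
  n_inputs < 0.7 * n_train
}

# Pooled R / scaled MSE over all targets for one model on one data subset.
# Each scaled column is mean-centered before pooling so the selection
# statistic measures within-target skill: without centering, shared
# column-mean structure lets even a constant-per-target predictor score a
# spuriously positive pooled correlation.
pooled_fit_stats <- function(model, X, Y) {
  pred <- predict(model, X)
  obs_s <- scale_minmax(as.matrix(Y), model$target_scaler)
  pred_s <- scale_minmax(pred, model$target_scaler)
  obs_c <- as.vector(sweep(obs_s, 2L, colMeans(obs_s)))
  pred_c <- as.vector(sweep(pred_s, 2L, colMeans(pred_s)))
  R <- if (sd(obs_c) > 0 && sd(pred_c) > 0) cor(obs_c, pred_c) else 0
  list(R = R, mse = mean((obs_s - pred_s)^2))
}

#' Neuron trimming: hidden-size selection
#'
#' Trains one network per candidate hidden size on a fixed random 70/30
#' split and selects, among the sizes whose test MSE is at most
#' `overfit_factor` times their training MSE (the overfit screen), the one
#' with the highest pooled test correlation; ties go to the smallest size
#' (parsimony).  If every size fails the screen, the best test R is returned
#' with a warning.
#'
#' @param X feature table (no missing values).
#' @param Y target matrix.
#' @param sizes candidate hidden sizes (default 3, 5, 7, 10).
#' @param seed RNG seed governing both the split and weight initialization.
#' @param train_frac training fraction.
#' @param max_epochs per-model epoch budget.
#' @param overfit_factor test-to-train MSE ratio admitted by the screen.
#' @return list with `model` (the selected `ann_model`), `trials` (per-size
#'   train/test R and scaled MSE), `size` (selected hidden size), `split`.
#' @export
neuron_trimming <- function(X, Y, sizes = c(3, 5, 7, 10), seed = 1L,
                            train_frac = 0.7, max_epochs = 300L,
                            overfit_factor = 3) {
  X <- as.data.frame(X); Y <- as.data.frame(Y)
  split <- split_samples(nrow(X), train_frac, seed = seed)
  models <- vector("list", length(sizes))
  trials <- data.frame(hidden_size = sizes, train_R = NA_real_,
                       train_mse = NA_real_, test_R = NA_real_,
                       test_mse = NA_real_, screened_out = FALSE)
  for (i in seq_along(sizes)) {
    m <- train_bayesian_regularization(X[split$train, ], Y[split$train, ],
                                       hidden_size = sizes[i], seed = seed,
                                       max_epochs = max_epochs)
    tr <- pooled_fit_stats(m, X[split$train, ], Y[split$train, ])
    te <- pooled_fit_stats(m, X[split$test, ], Y[split$test, ])
    trials$train_R[i] <- tr$R; trials$train_mse[i] <- tr$mse
    trials$test_R[i] <- te$R; trials$test_mse[i] <- te$mse
    trials$screened_out[i] <- te$mse > overfit_factor * tr$mse
    models[[i]] <- m
  }
  admissible <- which(!trials$screened_out)
  if (length(admissible) == 0L) {
    warning("all candidate sizes show test MSE > ", overfit_factor,
            "x train MSE; returning the best test R with an overfit warning")
    admissible <- seq_along(sizes)
  }
  # highest test R; ties broken towards the smallest size (sizes ascending)
  best <- admissible[order(-trials$test_R[admissible],
                           sizes[admissible])][1L]
  list(model = models[[best]], trials = trials, size = sizes[best],
       split = split)
}
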