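# Two-layer feedforward network (tan-sigmoid hidden layer, linear output
# layer) trained by Levenberg-Marquardt minimization of the regularized
# objective F = beta*E_D + alpha*E_W, with the evidence-framework
# re-estimation of alpha and beta (Bayesian regularization):
#   gamma = P - 2*alpha*tr(H^-1),  alpha <- gamma/(2*E_W),
#   beta <- (N - gamma)/(2*E_D)
# where E_D is the sum of squared residuals over all outputs, E_W the sum of
# squared weights, P the parameter count, N the number of residuals and
# H = 2*beta*J'J + 2*alpha*I the Gauss-Newton Hessian of F.

# ---- min-max scaling to [-1, 1] -------------------------------------------

make_scaler <- function(x) {
  x <- as.matrix(x)
  list(min = apply(x, 2L, min), max = apply(x, 2L, max))
}

scale_minmax <- function(x, scaler) {
  x <- as.matrix(x)
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1          # constant column maps to -1 (harmless)
  sweep(sweep(x, 2L, scaler$min, "-"), 2L, rng / 2, "/") - 1
}

unscale_minmax <- function(y, scaler) {
  y <- as.matrix(y)
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1
  sweep(sweep((y + 1) / 2, 2L, rng, "*"), 2L, scaler$min, "+")
}

# ---- parameter packing -----------------------------------------------------

pack_params <- function(W1, b1, W2, b2) c(as.vector(W1), b1, as.vector(W2), b2)

unpack_params <- function(w, d, m, K) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(m * d)], m, d); i <- i + m * d
  b1 <- w[i + seq_len(m)]; i <- i + m
  W2 <- matrix(w[i + seq_len(K * m)], K, m); i <- i + K * m
  b2 <- w[i + seq_len(K)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# forward pass in scaled space; returns outputs and hidden activations
ann_forward_scaled <- function(par, Xs) {
  A1 <- Xs %*% t(par$W1)
  H <- tanh(sweep(A1, 2L, par$b1, "+"))
  O <- sweep(H %*% t(par$W2), 2L, par$b2, "+")
  list(O = O, H = H)
}

# Jacobian of the stacked residual vector r = vec(Ys - O) (column-major over
# outputs) with respect to the packed parameters.
ann_jacobian <- function(par, Xs, H) {
  n <- nrow(Xs); d <- ncol(Xs)
  m <- length(par$b1); K <- length(par$b2)
  P <- m * d + m + K * m + K
  D <- 1 - H^2
  J <- matrix(0, n * K, P)
  off_b1 <- m * d
  off_W2 <- m * d + m
  off_b2 <- m * d + m + K * m
  for (k in seq_len(K)) {
    rows <- (k - 1L) * n + seq_len(n)
    A <- sweep(D, 2L, par$W2[k, ], "*")     # n x m
    for (l in seq_len(d)) {
      J[rows, (l - 1L) * m + seq_len(m)] <- -A * Xs[, l]
    }
    J[rows, off_b1 + seq_len(m)] <- -A
    J[rows, off_W2 + k + (seq_len(m) - 1L) * K] <- -H
    J[rows, off_b2 + k] <- -1
  }
  J
}

#' Train a Bayesian-regularized two-layer network
#'
#' Fits a feedforward network with `hidden_size` tan-sigmoid hidden units
#' and linear outputs by Levenberg-Marquardt steps on the regularized
#' objective `F = beta*E_D + alpha*E_W`.  Inputs and targets are min-max
#' scaled per column to `[-1, 1]` (scaling learned from the training rows);
#' weights start from a seeded small-uniform draw.  After every accepted
#' step the hyperparameters are re-estimated from the evidence framework
#' via the effective parameter count `gamma`.  Training stops on
#' `max_epochs`, a gradient below `grad_tol`, or damping overflow.
#'
#' @param X training inputs (data.frame or matrix, no missing values).
#' @param Y training targets (one column per target).
#' @param hidden_size number of hidden neurons.
#' @param seed RNG seed for weight initialization.
#' @param max_epochs epoch budget (default 300).
#' @param alpha either `NULL` (adaptive Bayesian regularization, the
#'   default) or a fixed non-negative value; `alpha = 0` reduces the trainer
#'   to plain Levenberg-Marquardt least squares.
#' @param grad_tol stop when the largest objective-gradient component falls
#'   below this.
#' @param mu0,mu_max initial and maximal Levenberg-Marquardt damping.
#' @return an object of class `ann_model` with weights, scalers,
#'   hyperparameters `alpha`/`beta`, the effective parameter count
#'   `gamma_eff` and a per-epoch `training_log`.
#' @export
train_bayesian_regularization <- function(X, Y, hidden_size, seed = 1L,
                                          max_epochs = 300L, alpha = NULL,
                                          grad_tol = 1e-7, mu0 = 5e-3,
                                          mu_max = 1e10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y)) stop("missing values in X or Y", call. = FALSE)
  if (nrow(X) != nrow(Y)) stop("X and Y row mismatch", call. = FALSE)
  stop_if_not_scalar_pos(hidden_size, "hidden_size")
  if (!overfit_guard(ncol(X), nrow(X))) {
    stop("overfit guard failed: need n_inputs < 0.7 * n_train (",
         ncol(X), " inputs vs ", nrow(X), " training rows)", call. = FALSE)
  }
  adaptive <- is.null(alpha)

  input_scaler <- make_scaler(X)
  target_scaler <- make_scaler(Y)
  Xs <- scale_minmax(X, input_scaler)
  Ys <- scale_minmax(Y, target_scaler)
  n <- nrow(Xs); d <- ncol(Xs)
  m <- as.integer(hidden_size); K <- ncol(Ys)
  P <- m * d + m + K * m + K
  N <- n * K

  w <- with_seed(seed, runif(P, -0.5, 0.5))
  a <- if (adaptive) 0 else alpha
  b <- 1
  mu <- mu0
  gamma <- P

  ed_ew <- function(w) {
    par <- unpack_params(w, d, m, K)
    O <- ann_forward_scaled(par, Xs)$O
    r <- as.vector(Ys - O)
    list(par = par, r = r, E_D = sum(r^2), E_W = sum(w^2))
  }
  st <- ed_ew(w)
  log_rows <- vector("list", max_epochs)
  stop_reason <- "max_epochs"

  for (epoch in seq_len(max_epochs)) {
    fw <- ann_forward_scaled(st$par, Xs)
    J <- ann_jacobian(st$par, Xs, fw$H)
    JJ <- crossprod(J)
    Jr <- crossprod(J, st$r)

    if (adaptive) {
      if (a > 0) {
        # with a > 0 the Gauss-Newton Hessian of F is positive definite
        Hfull <- 2 * b * JJ + diag(2 * a, P)
        tr_inv <- tryCatch(sum(diag(solve(Hfull))), error = function(e) NA)
        gamma <- if (is.finite(tr_inv)) P - 2 * a * tr_inv else gamma
      } else {
        gamma <- P   # alpha = 0: every parameter is effective
      }
      a <- gamma / (2 * max(st$E_W, 1e-12))
      b <- max(N - gamma, .Machine$double.eps) / (2 * max(st$E_D, 1e-12))
    }

    F_old <- b * st$E_D + a * st$E_W
    grad <- 2 * b * Jr + 2 * a * w
    if (max(abs(grad)) < grad_tol) {
      stop_reason <- "gradient"
      break
    }

    accepted <- FALSE
    F_new <- F_old
    while (mu <= mu_max) {
      Hm <- 2 * b * JJ + diag(2 * a + mu, P)
      step <- tryCatch(solve(Hm, -grad), error = function(e) NULL)
      if (!is.null(step)) {
        w_try <- w + as.vector(step)
        st_try <- ed_ew(w_try)
        F_new <- b * st_try$E_D + a * st_try$E_W
        if (is.finite(F_new) && F_new < F_old) {
          w <- w_try; st <- st_try
          mu <- max(mu / 10, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, F_before = F_old, F_after = F_new, E_D = st$E_D,
      E_W = st$E_W, alpha = a, beta = b, gamma = gamma, mu = mu,
      accepted = accepted
    )
    if (!accepted) {
      stop_reason <- "mu_overflow"
      break
    }
    if (!is.finite(st$E_D)) {
      stop("non-finite training loss; aborting (check input scaling)",
           call. = FALSE)
    }
  }

  par <- st$par
  structure(list(
    hidden_size = m, W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
    input_scaler = input_scaler, target_scaler = target_scaler,
    input_names = colnames(X), target_names = colnames(Y),
    alpha = a, beta = b, gamma_eff = gamma, n_params = P,
    stop_reason = stop_reason,
    training_log = do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])
  ), class = "ann_model")
}
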