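# Splitting, the overfit guard, the Bayesian-regularized trainer, trimming,
# regression reporting, PCA and grouped summaries.

test_that("splits are sized, disjoint, complete and seeded", {
  sp <- split_samples(150, 0.7, seed = 1)
  expect_length(sp$train, 105L)
  expect_length(sp$test, 45L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:150)
  expect_identical(sp, split_samples(150, 0.7, seed = 1))
  expect_false(identical(sp$train, split_samples(150, 0.7, seed = 2)$train))

  sp10 <- split_samples(10, 0.7, seed = 3)
  expect_length(sp10$train, 7L)
  expect_length(sp10$test, 3L)
  expect_error(split_samples(1), ">= 2")
  expect_error(split_samples(10, 1.2), "train_frac")
})

test_that("the overfit guard enforces inputs < 70% of training samples", {
  expect_true(overfit_guard(37, 105))
  expect_false(overfit_guard(74, 105))
  expect_true(overfit_guard(73, 105))    # 73 < 73.5 boundary
  expect_false(overfit_guard(21, 30))    # 21 = 0.7*30 exactly: not strictly below
})

test_that("the trainer fits a noise-free linear target essentially exactly", {
  set.seed(1)
  x <- matrix(runif(50), 50, 1, dimnames = list(NULL, "x"))
  y <- matrix(2 * x + 1, 50, 1, dimnames = list(NULL, "y"))
  m <- train_bayesian_regularization(x, y, 3, seed = 2)
  p <- predict(m, x)
  expect_lt(mean((p - y)^2), 1e-3)
  expect_gt(cor(as.vector(p), as.vector(y)), 0.999)
  # objective non-increasing over accepted steps; gamma bounded by P
  lg <- m$training_log
  expect_true(all(lg$F_after[lg$accepted] <= lg$F_before[lg$accepted]))
  expect_lte(m$gamma_eff, m$n_params)
  # determinism
  m2 <- train_bayesian_regularization(x, y, 3, seed = 2)
  expect_identical(m$W1, m2$W1)
  expect_error(train_bayesian_regularization(x[1:1, , drop = FALSE],
                                             y[1:1, , drop = FALSE], 3),
               "overfit guard")
})

test_that("with alpha = 0 the trainer matches an independent LM optimizer", {
  skip_if_not_installed("minpack.lm")
  x <- matrix(seq(-1, 1, length.out = 40), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- matrix(sin(2 * x), ncol = 1, dimnames = list(NULL, "y"))
  ymin <- min(y); ymax <- max(y)
  # oracle: generic LM on the identical residual function and initial point
  residual_fn <- function(w) {
    h <- tanh(x * w[1] + w[2])
    o <- as.vector(h * w[3] + w[4])
    as.vector(y) - ((o + 1) / 2 * (ymax - ymin) + ymin)
  }
  for (s in c(4, 7)) {
    m <- train_bayesian_regularization(x, y, 1, seed = s, alpha = 0,
                                       max_epochs = 400)
    ed_mine <- sum((predict(m, x) - y)^2)
    set.seed(s)
    w0 <- runif(4, -0.5, 0.5)
    fit <- minpack.lm::nls.lm(par = w0, fn = residual_fn,
                              control = minpack.lm::nls.lm.control(maxiter = 500))
    ed_oracle <- sum(residual_fn(fit$par)^2)
    expect_lt(abs(ed_mine - ed_oracle) / ed_oracle, 0.01)
  }
})

test_that("the forward pass matches hand arithmetic and degenerate nets", {
  # hand-computed 2-neuron, 1-input, 1-output example with identity scalers
  mdl <- structure(list(
    hidden_size = 2L,
    W1 = matrix(c(1, -0.5), 2, 1), b1 = c(0.2, 0.1),
    W2 = matrix(c(0.3, -0.7), 1, 2), b2 = 0.05,
    input_scaler = list(min = -1, max = 1),
    target_scaler = list(min = -1, max = 1),
    input_names = "x", target_names = "y"
  ), class = "ann_model")
  x <- matrix(0.4, 1, 1, dimnames = list(NULL, "x"))
  hand <- 0.3 * tanh(1 * 0.4 + 0.2) - 0.7 * tanh(-0.5 * 0.4 + 0.1) + 0.05
  expect_equal(unname(predict(mdl, x)[1, 1]), hand, tolerance = 1e-12)

  # zero output weights: output is constantly b2 (unscaled)
  mdl$W2 <- matrix(c(0, 0), 1, 2); mdl$b2 <- 0.3
  xs <- matrix(seq(-1, 1, 0.5), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(unname(predict(mdl, xs)[, 1]), rep(0.3, nrow(xs)),
               tolerance = 1e-12)

  # scale -> unscale round trip is the identity
  sc <- bovitals:::make_scaler(matrix(c(3, 9, -2, 14), 2, 2))
  z <- matrix(c(5, 7, 0, 1), 2, 2)
  expect_equal(bovitals:::unscale_minmax(bovitals:::scale_minmax(z, sc), sc),
               z, tolerance = 1e-12)
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(2)
  x <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- matrix(x[, 1] - 0.5 * x[, 2], 30, 1, dimnames = list(NULL, "y"))
  m <- train_bayesian_regularization(x, y, 3, seed = 1, max_epochs = 50)
  p <- withr::local_tempfile(fileext = ".json")
  write_ann_model(m, p)
  m2 <- read_ann_model(p)
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-10)
})

test_that("neuron trimming is deterministic and guards against fake skill", {
  d <- gen_herd_dataset(herd_spec(150, seed = 1))
  t1 <- neuron_trimming(d$features, d$targets, sizes = c(3, 5), seed = 9,
                        max_epochs = 60)
  t2 <- neuron_trimming(d$features, d$targets, sizes = c(3, 5), seed = 9,
                        max_epochs = 60)
  expect_identical(t1$size, t2$size)
  expect_identical(t1$trials, t2$trials)

  # pure-noise targets: no real skill on held-out data (3 quick seeds here;
  # the 20-seed null simulation runs in the acceptance suite)
  for (s in 1:3) {
    noise_y <- as.data.frame(matrix(rnorm(150 * 5, 0, 1), 150, 5))
    names(noise_y) <- target_columns()
    tn <- suppressWarnings(neuron_trimming(d$features, noise_y, sizes = 5,
                                           seed = s, max_epochs = 60))
    expect_lt(tn$trials$test_R[1], 0.3)
  }

  # impossible screen: falls back to best test R with a warning
  expect_warning(
    neuron_trimming(d$features, d$targets, sizes = 3, seed = 9,
                    max_epochs = 30, overfit_factor = 1e-6),
    "overfit"
  )
})

test_that("regression reports pool targets and count prediction-band outliers", {
  set.seed(5)
  obs <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, target_columns()))
  perfect <- regression_report(obs, obs)
  expect_equal(perfect$R, 1)
  expect_equal(perfect$slope_b, 1)
  expect_equal(perfect$MSE, 0)
  expect_equal(perfect$n_outliers, 0L)
  expect_equal(perfect$outlier_pct, 0)
  expect_equal(perfect$n_points, 300L)

  # Gaussian residuals: about 5 % fall outside the 95 % prediction band
  set.seed(6)
  o <- matrix(rnorm(10000), 2000, 5)
  p <- o + matrix(rnorm(10000, 0, 0.3), 2000, 5)
  rep_mc <- regression_report(o, p)
  expect_gt(rep_mc$outlier_pct, 4)
  expect_lt(rep_mc$outlier_pct, 6)
  # reported percentage is consistent with the counts at 1 decimal
  expect_equal(rep_mc$outlier_pct,
               round(100 * rep_mc$n_outliers / rep_mc$n_points, 1))

  # permutation invariance of the pooled statistics
  idx <- sample.int(2000)
  rep_perm <- regression_report(o[idx, ], p[idx, ])
  expect_equal(rep_perm$R, rep_mc$R)
  expect_equal(rep_perm$n_outliers, rep_mc$n_outliers)

  expect_error(regression_report(o, p[1:10, ]), "shape")
})

test_that("deployment evaluates held-out cows through the frozen model", {
  d <- gen_herd_dataset(herd_spec(150, seed = 2))
  tr <- neuron_trimming(d$features, d$targets, sizes = 3, seed = 2,
                        max_epochs = 60)
  d2 <- gen_herd_dataset(herd_spec(132, seed = 3))
  rep <- deploy(tr$model, d2$features, d2$targets)
  expect_equal(rep$n_points, 132L * 5L)
  expect_gt(rep$R, 0.8)
  expect_error(deploy(tr$model, d2$features[0, ], d2$targets[0, ]), "empty")
})

test_that("PCA summary standardizes, signs and orthonormalizes loadings", {
  # two perfectly correlated columns: PC1 explains everything
  x <- cbind(a = 1:50, b = 2 * (1:50) + 3)
  ps <- pca_summary(x)
  expect_equal(ps$explained_pct[1], 100)

  set.seed(8)
  iso <- matrix(rnorm(5000 * 5), 5000, 5)
  pi5 <- pca_summary(iso)
  expect_true(all(abs(pi5$explained_pct - 20) < 3))
  L <- pi5$loadings
  expect_lt(max(abs(crossprod(L) - diag(5))), 1e-10)
  # sign convention: dominant element of each component is positive
  expect_true(all(apply(L, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("grouped summaries report mean and SE with undefined single-member SE", {
  df <- data.frame(age = c(2, 2, 3), hr = c(10, 14, 9))
  s <- summarize_by_group(df, "age")
  r2 <- s[s$group == 2 & s$variable == "hr", ]
  expect_equal(r2$mean, 12)
  expect_equal(r2$se, 2)
  expect_true(is.na(s$se[s$group == 3]))

  # brute-force recomputation on a random fixture
  set.seed(10)
  big <- data.frame(age = sample(2:5, 200, replace = TRUE),
                    a = rnorm(200), b = runif(200))
  sb <- summarize_by_group(big, "age")
  for (g in unique(big$age)) {
    sub <- big$a[big$age == g]
    row <- sb[sb$group == g & sb$variable == "a", ]
    expect_equal(row$mean, mean(sub))
    expect_equal(row$se, sd(sub) / sqrt(length(sub)))
    expect_equal(row$n, length(sub))
  }
  expect_error(summarize_by_group(df, "breed"), "breed")
})
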