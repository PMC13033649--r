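# Denoising autoencoder: preprocessing, forward/backward passes, training,
# imputation and post-processing.

test_that("mean_fill substitutes observed column means only", {
  X <- matrix(c(2, 4, NA, 1, 1, 1), ncol = 2)
  colnames(X) <- c("a", "b")
  mf <- mean_fill(X)
  expect_equal(unname(mf$filled[3, "a"]), 3)  # mean of {2, 4}
  expect_equal(mf$filled[, "b"], c(1, 1, 1))
  expect_equal(unname(mf$fill_values), c(3, 1))

  complete <- matrix(rnorm(12), 4, 3)
  expect_identical(mean_fill(complete)$filled, complete)

  X[, "a"] <- NA
  expect_error(mean_fill(X), "a")
})

test_that("mean_fill values match a brute-force recount on a masked cohort", {
  fx <- make_masked_fixture(n = 50)
  X <- as.matrix(fx$masked[site_features()])
  mf <- mean_fill(X)
  for (f in colnames(X)) {
    obs <- X[!is.na(X[, f]), f]
    expect_equal(unname(mf$fill_values[f]), sum(obs) / length(obs))
  }
})

test_that("scaler uses population sd and round-trips within 1e-9", {
  X <- matrix(c(1, 2, 3), ncol = 1)
  sc <- fit_scaler(X)
  expect_equal(unname(sc$center), 2)
  expect_equal(unname(sc$scale), sqrt(2 / 3))
  expect_equal(drop(scaler_transform(sc, X)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  set.seed(1)
  Y <- matrix(rnorm(200 * 32, mean = 3, sd = 2), 200, 32)
  sc <- fit_scaler(Y)
  Z <- scaler_transform(sc, Y)
  expect_true(max(abs(colMeans(Z))) < 1e-9)
  expect_true(max(abs(sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2)) - 1)) < 1e-9)
  expect_true(max(abs(scaler_inverse(sc, Z) - Y)) < 1e-9)
})

test_that("constant columns degenerate to centering with a warning", {
  X <- cbind(c(5, 5, 5), c(1, 2, 3))
  expect_warning(sc <- fit_scaler(X), "constant")
  expect_equal(scaler_transform(sc, X)[, 1], c(0, 0, 0))
})

test_that("initialisation is seeded, bounded and bias-free", {
  cfg <- train_config(hidden_units = 18, seed = 21)
  p1 <- init_dae(cfg)
  p2 <- init_dae(cfg)
  expect_identical(p1, p2)
  expect_false(identical(p1, init_dae(train_config(hidden_units = 18,
                                                   seed = 22))))
  expect_equal(dim(p1$W1), c(32, 18))
  expect_equal(dim(p1$W2), c(18, 32))
  expect_true(all(abs(p1$W1) <= sqrt(6 / (32 + 18))))
  expect_true(all(abs(p1$W2) <= sqrt(6 / (18 + 32))))
  expect_equal(p1$b1, numeric(18))
  expect_equal(p1$b2, numeric(32))
})

test_that("forward pass matches an independent scalar re-implementation", {
  zero <- structure(list(W1 = matrix(0, 5, 2), b1 = numeric(2),
                         W2 = matrix(0, 2, 5), b2 = numeric(5)),
                    class = "perio_dae_params")
  X <- matrix(rnorm(15), 3, 5)
  fw <- dae_forward(zero, X)
  expect_true(all(fw$H == 0) && all(fw$Xhat == 0))

  # W1 = 0: the hidden layer saturates to tanh(0) = 0, rows of Xhat = b2
  zero$b2 <- rnorm(5)
  fw <- dae_forward(zero, X)
  for (i in 1:3) expect_equal(fw$Xhat[i, ], zero$b2)

  set.seed(33)
  params <- structure(list(W1 = matrix(rnorm(10, sd = 0.3), 5, 2),
                           b1 = rnorm(2), W2 = matrix(rnorm(10, sd = 0.3), 2, 5),
                           b2 = rnorm(5)), class = "perio_dae_params")
  fw <- dae_forward(params, X)
  for (i in 1:3) {
    h <- numeric(2)
    for (k in 1:2) {
      acc <- params$b1[k]
      for (j in 1:5) acc <- acc + X[i, j] * params$W1[j, k]
      h[k] <- tanh(acc)
    }
    for (j in 1:5) {
      acc <- params$b2[j]
      for (k in 1:2) acc <- acc + h[k] * params$W2[k, j]
      expect_equal(fw$Xhat[i, j], acc, tolerance = 1e-12)
    }
  }
  expect_true(all(abs(fw$H) < 1))
  expect_error(dae_forward(params, matrix(0, 2, 4)), "dimension")
})

test_that("loss is the row-wise squared norm averaged over rows", {
  X <- matrix(rnorm(8), 2, 4)
  expect_equal(dae_loss(X, X), 0)
  one <- matrix(0, 1, 3)
  hat <- matrix(c(0, 2, 0), 1, 3)
  expect_equal(dae_loss(hat, one), 4)
  # rows with squared norms 1 and 3 average to 2
  t2 <- matrix(0, 2, 2)
  h2 <- rbind(c(1, 0), c(sqrt(2), 1))
  expect_equal(dae_loss(h2, t2), 2)
  expect_error(dae_loss(matrix(0, 2, 2), matrix(0, 3, 2)), "dimension")
})

test_that("analytic gradients match central finite differences", {
  set.seed(44)
  n_feat <- 6; n_hid <- 4; n_row <- 5
  params <- structure(list(
    W1 = matrix(rnorm(n_feat * n_hid, sd = 0.4), n_feat, n_hid),
    b1 = rnorm(n_hid, sd = 0.2),
    W2 = matrix(rnorm(n_hid * n_feat, sd = 0.4), n_hid, n_feat),
    b2 = rnorm(n_feat, sd = 0.2)), class = "perio_dae_params")
  X <- matrix(rnorm(n_row * n_feat), n_row, n_feat)
  Tg <- matrix(rnorm(n_row * n_feat), n_row, n_feat)
  g <- dae_gradients(params, X, Tg)
  h <- 1e-5
  for (block in c("W1", "b1", "W2", "b2")) {
    for (idx in seq_along(params[[block]])) {
      plus <- params; plus[[block]][idx] <- plus[[block]][idx] + h
      minus <- params; minus[[block]][idx] <- minus[[block]][idx] - h
      fd <- (dae_loss(dae_forward(plus, X)$Xhat, Tg) -
             dae_loss(dae_forward(minus, X)$Xhat, Tg)) / (2 * h)
      expect_lt(abs(g[[block]][idx] - fd), 1e-6 * max(1, abs(fd)))
    }
  }
})

test_that("gradients vanish at a stationary point and on cut signal paths", {
  # exact reconstruction: constant target rows equal to b2 with dead encoder
  params <- structure(list(W1 = matrix(0, 4, 2), b1 = numeric(2),
                           W2 = matrix(0, 2, 4), b2 = c(1, -1, 2, 0)),
                      class = "perio_dae_params")
  X <- matrix(rnorm(12), 3, 4)
  Tg <- matrix(params$b2, 3, 4, byrow = TRUE)
  g <- dae_gradients(params, X, Tg)
  for (block in c("W1", "b1", "W2", "b2")) {
    expect_true(all(g[[block]] == 0))
  }

  # W2 = 0, b2 = 0: no path back to W1; b2 gradient is -2 x mean residual
  params$b2 <- numeric(4)
  Tg <- matrix(rnorm(12), 3, 4)
  g <- dae_gradients(params, X, Tg)
  expect_true(all(g$W1 == 0))
  expect_equal(g$b2, -2 * colMeans(Tg))
})

test_that("training is deterministic and degenerate configs behave", {
  fx <- make_masked_fixture(n = 40)
  cfg0 <- train_config(epochs = 0, seed = 8)
  fit0 <- train_dae(fx$masked, cfg0)
  expect_identical(fit0$params, init_dae(cfg0))
  expect_equal(nrow(fit0$trace), 0)

  flat <- train_dae(fx$masked, train_config(epochs = 15, learning_rate = 0,
                                            seed = 8))
  expect_true(all(flat$trace$loss == flat$trace$loss[1]))

  a <- train_dae(fx$masked, train_config(epochs = 20, seed = 8))
  b <- train_dae(fx$masked, train_config(epochs = 20, seed = 8))
  expect_identical(a$params, b$params)
  expect_identical(a$trace, b$trace)
  expect_equal(a$trace$loss_per_entry, a$trace$loss / 32)
})

test_that("training against the ground truth requires the complete cohort", {
  fx <- make_masked_fixture(n = 30)
  expect_error(train_dae(fx$masked, train_config(epochs = 2),
                         target = "truth"), "complete cohort")
  fit <- train_dae(fx$masked, train_config(epochs = 5, seed = 2),
                   target = "truth", truth = fx$cohort)
  expect_s3_class(fit, "perio_dae")
})

test_that("imputation replaces masked cells only, in both modes", {
  fx <- make_masked_fixture(n = 60)
  fit <- train_dae(fx$masked, train_config(seed = 5))
  for (mode in c("raw", "clinical")) {
    imp <- impute_dae(fit, fx$masked, fx$mask, post_process = mode)
    expect_false(anyNA(imp[site_features()]))
    expect_observed_preserved(imp, fx$masked, fx$mask)
  }
  # nothing to impute: identity
  none <- apply_mcar(fx$cohort, rate = 0, seed = 1)
  imp <- impute_dae(fit, none$masked, none$mask)
  expect_identical(imp[names(fx$cohort)], fx$cohort[names(fx$cohort)])
})

test_that("clinical post-processing lands in chart-valid ranges", {
  fx <- make_masked_fixture(n = 60)
  fit <- train_dae(fx$masked, train_config(seed = 5))
  imp <- impute_dae(fit, fx$masked, fx$mask, post_process = "clinical")
  for (f in site_features()) {
    vals <- imp[[f]][fx$mask[, f]]
    switch(feature_category(f),
      ProbingDepth = expect_true(all(vals >= 1)),
      AttachmentLoss = expect_true(all(vals >= 0)),
      Furcation = expect_true(all(vals %in% 0:3)),
      BleedingOnProbing = expect_true(all(vals %in% 0:1)))
  }
})

test_that("a fully masked patient is imputed at the zero-input reconstruction", {
  cohort <- make_cohort(50, seed = 9)
  mc <- apply_mcar(cohort, rate = 0.1, seed = 10)
  mc$mask[1, ] <- TRUE
  for (f in site_features()) mc$masked[[f]][1] <- NA_real_
  fit <- train_dae(mc$masked, train_config(seed = 11))
  imp <- impute_dae(fit, mc$masked, mc$mask)
  # mean-filling a fully masked row puts it at the column means, which are
  # the scaler centers, so its standardised input is exactly zero
  z0 <- matrix(0, 1, 32, dimnames = list(NULL, site_features()))
  expected <- scaler_inverse(fit$scaler, dae_forward(fit$params, z0)$Xhat)
  got <- as.numeric(imp[1, site_features()])
  expect_equal(got, unname(drop(expected)), tolerance = 1e-9)
})
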