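test_that("Matern 5/2 kernel has the closed form's signature values", {
  expect_equal(matern52(0, 0, 1, amplitude = 2.5)[1, 1], 2.5)
  # isotropic l = 1, |x - x'| = 1
  expect_equal(matern52(0, 1, 1)[1, 1],
               (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)),
               tolerance = 1e-12)
  expect_equal(matern52(0, 1, 1)[1, 1], 0.52400, tolerance = 1e-4)

  r <- seq(0, 10, by = 0.1)
  k <- matern52(matrix(r), matrix(0), 1)[, 1]
  expect_true(all(diff(k) < 0))
  expect_lt(matern52(0, 100, 1)[1, 1], 1e-10)
  expect_error(matern52(0, 1, -1), "positive")
})

test_that("Gram matrices on random point sets are symmetric PSD", {
  for (seed in 1:5) {
    X <- withr::with_seed(seed, matrix(runif(30 * 4), ncol = 4))
    ls <- withr::with_seed(seed, runif(4, 0.1, 2))
    K <- matern52(X, X, ls, amplitude = 1.7)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("posterior mean and sd agree with a dense-solve oracle", {
  for (seed in 1:3) {
    n <- c(5, 12, 20)[seed]
    X <- withr::with_seed(seed, matrix(runif(n * 3), ncol = 3))
    y <- withr::with_seed(seed + 100, rnorm(n, 5, 2))
    hp <- list(length_scales = c(0.3, 0.8, 1.5), amplitude = 2,
               noise = 0.05, mean = 4)
    m <- gp_with_hyperparams(X, y, hp)
    Xs <- withr::with_seed(seed + 200, matrix(runif(15 * 3), ncol = 3))
    oracle <- dense_gp_oracle(X, y, hp, Xs)
    pred <- predict(m, Xs)
    expect_equal(pred$mean, oracle$mean, tolerance = 1e-8)
    expect_equal(pred$sd, oracle$sd, tolerance = 1e-8)
  }
})

test_that("GP interpolates as noise vanishes and reverts to the prior", {
  X <- matrix(seq(0.1, 0.9, length.out = 5), ncol = 1)
  y <- c(2, 5, 3, 8, 6)
  hp <- list(length_scales = 0.2, amplitude = 4, noise = 1e-10, mean = 4)
  m <- gp_with_hyperparams(X, y, hp)
  at_train <- predict(m, X)
  expect_equal(at_train$mean, y, tolerance = 1e-3)

  far <- predict(m, matrix(50, ncol = 1))
  expect_equal(far$mean, hp$mean, tolerance = 1e-6)
  expect_equal(far$sd, sqrt(hp$amplitude), tolerance = 1e-6)

  # posterior sd never exceeds the prior sd
  grid <- matrix(seq(0, 1, length.out = 101), ncol = 1)
  expect_true(all(predict(m, grid)$sd <=
                    sqrt(hp$amplitude + hp$noise) + 1e-9))
})

test_that("log marginal likelihood matches brute-force normal densities", {
  # single observation at the mean with unit total variance
  m1 <- list(X = matrix(0.5, ncol = 1), y = 3,
             hyperparams = list(length_scales = 1, amplitude = 0.6,
                                noise = 0.4, mean = 3))
  expect_equal(log_marginal_likelihood(m1), -0.5 * log(2 * pi),
               tolerance = 1e-6)

  X <- withr::with_seed(9, matrix(runif(8), ncol = 2))
  y <- withr::with_seed(10, rnorm(4, 2, 1))
  hp <- list(length_scales = c(0.5, 1.2), amplitude = 1.3, noise = 0.2,
             mean = 1.5)
  expect_equal(log_marginal_likelihood(list(X = X, y = y, hyperparams = hp)),
               dense_lml_oracle(X, y, hp), tolerance = 1e-8)

  # duplicating an observation keeps agreement with the oracle
  X2 <- rbind(X, X[1, ])
  y2 <- c(y, y[1])
  expect_equal(log_marginal_likelihood(list(X = X2, y = y2,
                                            hyperparams = hp)),
               dense_lml_oracle(X2, y2, hp), tolerance = 1e-8)
})

test_that("fitting recovers a smooth function and is seed-deterministic", {
  X <- matrix(seq(0, 1, length.out = 25), ncol = 1)
  y <- sin(2 * pi * X[, 1])
  m <- gp_fit(X, y, restarts = 4, seed = 1)
  Xs <- matrix(seq(0.01, 0.99, length.out = 100), ncol = 1)
  rmse <- sqrt(mean((predict(m, Xs)$mean - sin(2 * pi * Xs[, 1]))^2))
  expect_lt(rmse, 0.05)

  m2 <- gp_fit(X, y, restarts = 4, seed = 1)
  expect_identical(m$hyperparams, m2$hyperparams)
})

test_that("constant targets are recovered flat", {
  X <- withr::with_seed(3, matrix(runif(20), ncol = 2))
  m <- gp_fit(X, rep(7, 10), restarts = 2, seed = 2)
  pred <- predict(m, withr::with_seed(4, matrix(runif(10), ncol = 2)))
  expect_equal(pred$mean, rep(7, 5), tolerance = 0.05)
})

test_that("predictions are invariant to permuting the training rows", {
  X <- withr::with_seed(5, matrix(runif(30), ncol = 3))
  y <- withr::with_seed(6, rnorm(10))
  hp <- list(length_scales = c(0.4, 0.7, 1), amplitude = 1, noise = 0.1,
             mean = 0)
  perm <- withr::with_seed(7, sample(10))
  m1 <- gp_with_hyperparams(X, y, hp)
  m2 <- gp_with_hyperparams(X[perm, ], y[perm], hp)
  Xs <- withr::with_seed(8, matrix(runif(12), ncol = 3))
  expect_equal(predict(m1, Xs)$mean, predict(m2, Xs)$mean,
               tolerance = 1e-10)
  expect_equal(predict(m1, Xs)$sd, predict(m2, Xs)$sd, tolerance = 1e-10)
})

test_that("length scales are recovered within a factor of 3 from prior draws", {
  true_ls <- c(0.15, 0.6)
  X <- withr::with_seed(21, matrix(runif(200), ncol = 2))
  K <- matern52(X, X, true_ls, amplitude = 4)
  diag(K) <- diag(K) + 1e-6
  y <- withr::with_seed(22, as.numeric(t(chol(K)) %*% rnorm(100)))
  m <- gp_fit(X, y, restarts = 6, seed = 23)
  ratio <- m$hyperparams$length_scales / true_ls
  expect_true(all(ratio > 1 / 3 & ratio < 3))
})

test_that("fit validates its inputs", {
  expect_error(gp_fit(matrix(0.5), 1), "at least 2")
  expect_error(gp_fit(matrix(c(0.1, 5), ncol = 1), c(1, 2), seed = 1),
               "unit cube")
})

test_that("checkpoints reload to identical predictions", {
  X <- withr::with_seed(31, matrix(runif(24), ncol = 2))
  y <- withr::with_seed(32, rnorm(12, 6, 2))
  m <- gp_fit(X, y, restarts = 2, seed = 33)
  path <- withr::local_tempfile(fileext = ".json")
  write_gp_checkpoint(m, path)
  m2 <- read_gp_checkpoint(path)
  Xs <- withr::with_seed(34, matrix(runif(10), ncol = 2))
  expect_equal(predict(m2, Xs), predict(m, Xs), tolerance = 1e-12)
})

test_that("tidy and glance expose the hyperparameters", {
  X <- withr::with_seed(41, matrix(runif(20), ncol = 2))
  y <- withr::with_seed(42, rnorm(10))
  m <- gp_fit(X, y, restarts = 2, seed = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 2 + 3)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$nobs, 10)
  expect_equal(gl$logLik, log_marginal_likelihood(m))
})
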