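test_that("impute_mean fills with cross-day column means", {
  X <- rbind(c(60, 1), c(70, 2), c(80, 3), c(NA, 4))
  r <- impute_mean(X)
  expect_equal(r$filled[4L, 1L], 70)
  expect_equal(nrow(r$imputed_cells), 1L)
  expect_equal(r$imputed_cells$value, 70)

  # no missing -> identity, no imputed cells
  Y <- matrix(1:6, 2L)
  r2 <- impute_mean(Y)
  expect_equal(r2$filled, matrix(as.numeric(1:6), 2L))
  expect_equal(nrow(r2$imputed_cells), 0L)

  # single observed value in a column
  Z <- rbind(c(55, 1), c(NA, 2), c(NA, 3))
  expect_equal(impute_mean(Z)$filled[, 1L], c(55, 55, 55))

  expect_error(impute_mean(rbind(c(NA, 1), c(NA, 2))),
               class = "binimpute_degenerate_column")
})

test_that("impute_knn nearest-donor behaviour and degenerate equivalence", {
  # zero-distance donor is copied with k = 1
  A <- rbind(c(5, 6, NA), c(5, 6, 9), c(50, 60, 70))
  expect_equal(impute_knn(A, k = 1L)$filled[1L, 3L], 9)

  # derived example: target shares (0,0) with first donor
  B <- rbind(c(0, 0, NA), c(0, 0, 4), c(3, 3, 8))
  expect_equal(impute_knn(B, k = 1L)$filled[1L, 3L], 4)

  # k = D-1 with uniform weights and fully observed donors == column mean
  set.seed(3)
  X <- matrix(rnorm(8 * 6, 60, 5), 8L)
  X[2L, c(1L, 4L)] <- NA
  expect_equal(impute_knn(X, k = 7L)$filled, impute_mean(X)$filled)

  expect_warning(r <- impute_knn(B, k = 10L), "clipped")
  expect_false(anyNA(r$filled))
})

test_that("impute_knn matches a brute-force oracle on random instances", {
  for (seed in 1:8) {
    X <- random_masked_matrix(7L, 5L, frac = 0.2, seed = seed)
    k <- 1L + seed %% 4L
    expect_equal(impute_knn(X, k = k)$filled, knn_oracle(X, k),
                 tolerance = 1e-12)
  }
})

test_that("fit_em on a fully observed matrix is a one-step fit", {
  X <- matrix(rnorm(40, 70, 4), 10L)
  m <- fit_em(X, shrinkage = 0)
  expect_equal(m$mu, colMeans(X))
  expect_equal(m$n_iterations, 1L)
  expect_true(m$converged)
  expect_equal(m$filled, X)
})

test_that("EM recovers the closed-form conditional mean on a linear system", {
  x1 <- c(60, 65, 70, 72, 80, 58, 66)
  X <- cbind(x1, x1 + 5)
  X[3L, 2L] <- NA
  m <- impute_em(X, shrinkage = 0, tol = 1e-10, max_iter = 300L)
  expect_equal(m$filled[3L, 2L], 75, tolerance = 1e-6)
  # conditional mean with col2 = 2*col1 as well
  Y <- cbind(x1, 2 * x1)
  Y[5L, 2L] <- NA
  m2 <- impute_em(Y, shrinkage = 0, tol = 1e-10, max_iter = 300L)
  expect_equal(m2$filled[5L, 2L], 160, tolerance = 1e-5)
})

test_that("EM log-likelihood trace is non-decreasing (spot check)", {
  for (seed in 1:25) {
    X <- random_masked_matrix(15L, 6L, frac = 0.15, seed = seed)
    m <- fit_em(X, shrinkage = 0, tol = 0, max_iter = 15L)
    expect_gte(min(diff(m$loglik_trace)), -1e-8)
  }
})

test_that("impute_em on a single column equals the column mean", {
  X <- matrix(c(60, NA, 70, 80, NA), ncol = 1L)
  expect_equal(impute_em(X)$filled, impute_mean(X)$filled)
})

test_that("dense and low-rank EM paths agree", {
  X <- random_masked_matrix(10L, 30L, frac = 0.05, seed = 9L)
  a <- fit_em(X, shrinkage = 0.2, tol = 1e-10, max_iter = 40L,
              method = "dense")
  b <- fit_em(X, shrinkage = 0.2, tol = 1e-10, max_iter = 40L,
              method = "lowrank")
  expect_equal(a$filled, b$filled, tolerance = 1e-9)
  expect_equal(a$sigma, b$sigma, tolerance = 1e-9)
  expect_equal(a$loglik_trace, b$loglik_trace, tolerance = 1e-9)
})

test_that("impute_iterative: initialization, convergence, singularity", {
  X <- random_masked_matrix(8L, 4L, frac = 0.15, seed = 2L)
  # round 0 is the column-mean initialization
  r0 <- impute_iterative(X, max_iter = 0L)
  expect_equal(r0$filled, impute_mean(X)$filled)
  expect_equal(r0$n_iterations, 0L)

  # exact relation col2 = 2 col1 recovered as ridge -> 0
  x1 <- c(4, 7, 9, 12, 15)
  Y <- cbind(x1, 2 * x1)
  Y[2L, 2L] <- NA
  Y[2L, 1L] <- 10
  r <- impute_iterative(Y, ridge = 1e-8, tol = 1e-10)
  expect_equal(r$filled[2L, 2L], 20, tolerance = 1e-4)

  # identical predictor columns are singular without a ridge
  Z <- cbind(x1, x1, c(NA, 2, 3, 4, 5))
  expect_error(impute_iterative(Z, ridge = 0),
               class = "binimpute_numerical_error")

  expect_equal(impute_iterative(matrix(1:9, 3L))$filled,
               matrix(as.numeric(1:9), 3L))
})

test_that("impute_forest basics and determinism", {
  expect_error(impute_forest(matrix(rnorm(20), 5L), n_trees = 0L),
               class = "binimpute_config_error")
  # constant target column -> the constant
  X <- cbind(rnorm(6, 50, 5), rep(7, 6))
  X[3L, 2L] <- NA
  expect_equal(impute_forest(X, n_trees = 25L)$filled[3L, 2L], 7)
  # bitwise determinism under a fixed seed
  Y <- random_masked_matrix(8L, 5L, frac = 0.15, seed = 13L)
  a <- impute_forest(Y, n_trees = 30L, seed = 99L)
  b <- impute_forest(Y, n_trees = 30L, seed = 99L)
  expect_identical(a$filled, b$filled)
  c <- impute_forest(Y, n_trees = 30L, seed = 100L)
  expect_false(identical(a$filled, c$filled))
  # no missing -> identity
  Z <- matrix(rnorm(24), 6L)
  expect_equal(impute_forest(Z)$filled, Z)
})

test_that("all imputers preserve observed cells and fill everything", {
  X <- random_masked_matrix(9L, 6L, frac = 0.15, seed = 21L)
  obs <- !is.na(X)
  for (alg in c("si", "knn", "em", "ii", "rf")) {
    r <- impute_by_name(X, alg, params = list(n_trees = 20L))
    expect_false(anyNA(r$filled), info = alg)
    expect_equal(r$filled[obs], X[obs], info = alg)
    expect_equal(nrow(r$imputed_cells), sum(!obs), info = alg)
  }
  expect_error(impute_by_name(X, "magic"), class = "binimpute_config_error")
})

test_that("mean, EM and iterative imputation are row-equivariant", {
  X <- random_masked_matrix(7L, 5L, frac = 0.15, seed = 31L)
  perm <- c(3L, 1L, 7L, 5L, 2L, 6L, 4L)
  for (alg in c("si", "em", "ii")) {
    a <- impute_by_name(X, alg)$filled
    b <- impute_by_name(X[perm, ], alg)$filled
    expect_equal(b, a[perm, ], tolerance = 1e-8, info = alg)
  }
})
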