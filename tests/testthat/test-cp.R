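test_that("reconstruction matches the brute-force rank-one sum", {
  set.seed(51)
  A <- matrix(rnorm(10), 5, 2); B <- matrix(rnorm(8), 4, 2)
  C <- matrix(rnorm(6), 3, 2)
  m <- structure(list(weights = c(2, -1), A = A, B = B, C = C),
                 class = "cp_model")
  expect_lt(max(abs(reconstruct(m) -
                      brute_force_reconstruct(c(2, -1), A, B, C))), 1e-12)

  m0 <- structure(list(weights = c(0, 0), A = A, B = B, C = C),
                  class = "cp_model")
  expect_true(all(reconstruct(m0) == 0))
  e1 <- structure(list(weights = 1, A = cbind(c(1, 0)), B = cbind(c(1, 0)),
                       C = cbind(c(1, 0))), class = "cp_model")
  X <- reconstruct(e1)
  expect_equal(X[1, 1, 1], 1)
  expect_equal(sum(X != 0), 1L)
  bad <- m; bad$B <- B[, 1, drop = FALSE]
  expect_error(reconstruct(bad), "conformable")
})

test_that("explained fit satisfies its closed-form identities", {
  X <- small_random_tensor(5, 4, 3, seed = 52)
  expect_equal(fit_percent(X, X), 100)
  expect_equal(fit_percent(X, array(0, dim = dim(X))), 0)
  toy <- array(2, dim = c(1, 1, 1))
  expect_equal(fit_percent(toy, array(1, dim = c(1, 1, 1))), 75)
  expect_error(fit_percent(array(0, dim = c(2, 1, 1)), toy), "shapes")
  expect_error(fit_percent(array(0, dim = c(1, 1, 1)),
                           array(1, dim = c(1, 1, 1))), "zero")
})

test_that("a noiseless rank-1 tensor is fitted exactly", {
  set.seed(53)
  truth <- list(weights = 2.5,
                A = cbind(rnorm(6) / sqrt(6)),
                B = cbind(rnorm(5) / sqrt(5)),
                C = cbind(abs(rnorm(4))))
  truth$C <- truth$C / sqrt(sum(truth$C^2))
  X <- brute_force_reconstruct(truth$weights, truth$A, truth$B, truth$C)
  m <- fit_cp(X, quick_opts(1))
  expect_gt(m$fit, 100 - 1e-6)
})

test_that("planted rank-2 factors are recovered after matching", {
  tr <- planted_rank2()
  m <- fit_cp(tr$X, quick_opts(2, n_starts = 6, max_iters = 2000))
  expect_gt(m$fit, 100 - 1e-4)
  expect_true(all(matched_congruences(m, tr) > 0.99))
})

test_that("fitted models are normalized, ordered and time-non-negative", {
  tr <- planted_rank2()
  set.seed(54)
  Xn <- add_noise(tr$X, 0.1)
  m <- fit_cp(Xn, quick_opts(2, n_starts = 4, max_iters = 1000))
  expect_equal(colSums(m$A^2), rep(1, 2), tolerance = 1e-10)
  expect_equal(colSums(m$B^2), rep(1, 2), tolerance = 1e-10)
  expect_equal(colSums(m$C^2), rep(1, 2), tolerance = 1e-10)
  expect_true(all(diff(m$weights) <= 0) && all(m$weights >= 0))
  expect_true(all(m$C >= 0))
  expect_true(all(colSums(m$B) >= 0))
})

test_that("objective decreases monotonically along one ALS trajectory", {
  tr <- planted_rank2()
  set.seed(55)
  Xn <- add_noise(tr$X, 0.2)
  m <- fit_cp(Xn, quick_opts(2, n_starts = 1, max_iters = 400))
  expect_true(all(diff(m$trace) <= 1e-10 * pmax(m$trace[-length(m$trace)], 1)))
  # masked EM path is monotone too
  set.seed(56)
  W <- make_missing_mask(dim(Xn), 0.2)
  mm <- fit_cp(Xn, quick_opts(2, n_starts = 1, max_iters = 400), mask = W)
  expect_true(all(diff(mm$trace) <= 1e-10 * pmax(mm$trace[-length(mm$trace)], 1)))
})

test_that("best-of-multistart fit is non-decreasing in R", {
  Y <- small_random_tensor(7, 6, 5, seed = 57)
  fits <- vapply(1:3, function(R)
    fit_cp(Y, quick_opts(R, n_starts = 10, max_iters = 800))$fit, numeric(1))
  expect_true(all(diff(fits) >= -1e-8))
})

test_that("all-ones mask reproduces the unmasked objective", {
  tr <- planted_rank2(10, 7, 8, seed = 58)
  set.seed(58)
  Xn <- add_noise(tr$X, 0.15)
  m1 <- fit_cp(Xn, quick_opts(2, n_starts = 3, max_iters = 1500))
  m2 <- fit_cp(Xn, quick_opts(2, n_starts = 3, max_iters = 1500),
               mask = array(1, dim = dim(Xn)))
  expect_lt(abs(m1$objective - m2$objective) / m1$objective, 1e-8)
})

test_that("reconstruction is invariant to lambda/column rescaling", {
  set.seed(59)
  m <- structure(list(weights = c(3, 2),
                      A = matrix(rnorm(8), 4, 2),
                      B = matrix(rnorm(6), 3, 2),
                      C = matrix(rnorm(10), 5, 2)), class = "cp_model")
  m2 <- m
  m2$weights <- m$weights * c(4, 0.5)
  m2$A[, 1] <- m$A[, 1] / 2; m2$B[, 1] <- m$B[, 1] / 2
  m2$C[, 2] <- m$C[, 2] * 2
  expect_equal(reconstruct(m), reconstruct(m2), tolerance = 1e-12)
})

test_that("missing entries of a noiseless rank-2 tensor are recovered", {
  tr <- planted_rank2(14, 9, 11, seed = 60)
  set.seed(60)
  W <- make_missing_mask(dim(tr$X), 0.2)
  m <- fit_cp(tr$X, quick_opts(2, n_starts = 4, max_iters = 3000, tol = 1e-12),
              mask = W)
  Xh <- reconstruct(m)
  rel <- sqrt(sum((Xh[W == 0] - tr$X[W == 0])^2) / sum(tr$X[W == 0]^2))
  expect_lt(rel, 1e-4)
})

test_that("fits are deterministic given the seed and reject bad input", {
  Y <- small_random_tensor(6, 5, 4, seed = 61)
  m1 <- fit_cp(Y, quick_opts(2, n_starts = 3, seed = 7))
  m2 <- fit_cp(Y, quick_opts(2, n_starts = 3, seed = 7))
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$A, m2$A)
  Ybad <- Y; Ybad[2, 2, 2] <- Inf
  expect_error(fit_cp(Ybad, quick_opts(1)), "non-finite")
})
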