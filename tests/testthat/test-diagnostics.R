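test_that("core consistency is 100 for fitted 1-component models", {
  for (seed in c(81, 82)) {
    Y <- small_random_tensor(6, 5, 4, seed = seed)
    m <- fit_cp(Y, quick_opts(1, n_starts = 3))
    expect_equal(core_consistency(Y, m), 100, tolerance = 1e-6)
  }
})

test_that("core consistency is 100 for an exact-rank fit and collapses when
           overfactored", {
  tr <- planted_rank2()
  m <- fit_cp(tr$X, quick_opts(2, n_starts = 6, max_iters = 2000))
  expect_equal(core_consistency(tr$X, m), 100, tolerance = 1e-6)
  expect_error(core_consistency(array(0, dim = c(2, 2, 2)),
                                structure(list(weights = rep(1, 3),
                                               A = matrix(1, 2, 3),
                                               B = matrix(1, 2, 3),
                                               C = matrix(1, 2, 3)),
                                          class = "cp_model")),
               "ill-posed")
})

test_that("cosine similarity obeys its identities", {
  u <- c(2, -1, 3)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(u, -u), -1)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), u[1:2]), "zero")
})

test_that("congruence matrix matches the direct triple-product oracle", {
  set.seed(83)
  m <- structure(list(weights = c(3, 2, 1),
                      A = matrix(rnorm(15), 5, 3),
                      B = matrix(rnorm(12), 4, 3),
                      C = matrix(rnorm(18), 6, 3)), class = "cp_model")
  TC <- congruence_matrix(m)
  cosine <- function(M, i, j) sum(M[, i] * M[, j]) /
    sqrt(sum(M[, i]^2) * sum(M[, j]^2))
  for (i in 1:3) for (j in 1:3) {
    direct <- cosine(m$A, i, j) * cosine(m$B, i, j) * cosine(m$C, i, j)
    expect_equal(TC[i, j], direct, tolerance = 1e-12)
  }
  expect_equal(TC, t(TC))
  expect_equal(diag(TC), rep(1, 3))
})

test_that("duplicate and single-mode-orthogonal components give TC 1 and 0", {
  a <- c(1, 2) / sqrt(5); b <- c(2, 1) / sqrt(5); cc <- c(1, 1) / sqrt(2)
  dup <- structure(list(weights = c(1, 1), A = cbind(a, a), B = cbind(b, b),
                        C = cbind(cc, cc)), class = "cp_model")
  expect_equal(congruence_matrix(dup)[1, 2], 1, tolerance = 1e-12)
  orth <- dup
  orth$B <- cbind(c(1, 0), c(0, 1))
  expect_equal(congruence_matrix(orth)[1, 2], 0, tolerance = 1e-12)
  tc <- tucker_congruence(dup)
  expect_equal(tc$tc, 1)
  expect_false(tc$degenerate)
})

test_that("tensor completion score follows its definition", {
  X <- small_random_tensor(4, 3, 3, seed = 84)
  W <- array(1, dim = dim(X)); W[1, 1, 1] <- 0
  expect_equal(tcs(X, X, W), 0)
  expect_equal(tcs(X, array(0, dim = dim(X)), W), 1)
  # toy: missing entry has value 2, estimate 1 -> |1 - 2| / |2| = 0.5
  Xt <- array(c(1, 2), dim = c(2, 1, 1))
  Ht <- array(c(9, 1), dim = c(2, 1, 1))
  Wt <- array(c(1, 0), dim = c(2, 1, 1))
  expect_equal(tcs(Xt, Ht, Wt), 0.5)
  expect_error(tcs(X, X, array(1, dim = dim(X))), "no entries")
  # invariant to arbitrary changes at observed entries
  H2 <- X + array(runif(36), dim = dim(X)) * W
  expect_equal(tcs(X, H2, W), 0)
})

test_that("identical model specs give vanishing paired TCS differences", {
  tr <- planted_rank2(10, 6, 8, seed = 85)
  specs <- list(cp_spec(2, n_starts = 2, max_iters = 1000, tol = 1e-11,
                        label = "a"),
                cp_spec(2, n_starts = 2, max_iters = 1000, tol = 1e-11,
                        label = "b"))
  cv <- crossval_compare(tr$X, specs, eta = 0, missing_fraction = 0.15,
                         n_reps = 6, seed = 85)
  expect_lt(max(abs(cv$tcs[, 1] - cv$tcs[, 2])), 1e-4)
})

test_that("the true-rank model beats an overfactored one on noisy held-out
           entries", {
  # overfactoring hurts through overfitting, so the comparison needs noise
  # for the extra component to chase
  tr <- planted_rank2(12, 8, 10, seed = 86)
  specs <- list(cp_spec(2, n_starts = 2, max_iters = 1500, tol = 1e-11),
                cp_spec(3, n_starts = 2, max_iters = 1500, tol = 1e-11))
  cv <- crossval_compare(tr$X, specs, eta = 0.3, missing_fraction = 0.2,
                         n_reps = 20, seed = 86)
  expect_gte(sum(cv$tcs[, 1] <= cv$tcs[, 2] + 1e-12), 15)
})

test_that("cross-validation is bit-identical on rerun with the same seed", {
  tr <- planted_rank2(8, 6, 7, seed = 87)
  specs <- list(cp_spec(1, n_starts = 2, max_iters = 500),
                cp_spec(2, n_starts = 2, max_iters = 500))
  cv1 <- crossval_compare(tr$X, specs, eta = 0.2, missing_fraction = 0.2,
                          n_reps = 5, seed = 87)
  cv2 <- crossval_compare(tr$X, specs, eta = 0.2, missing_fraction = 0.2,
                          n_reps = 5, seed = 87)
  expect_identical(cv1$tcs, cv2$tcs)
  expect_identical(cv1$paired_p, cv2$paired_p)
})

test_that("reports serialize to delimited text and JSON", {
  tr <- planted_rank2(8, 6, 7, seed = 88)
  specs <- list(cp_spec(1, n_starts = 1, max_iters = 300),
                cp_spec(2, n_starts = 1, max_iters = 300))
  cv <- crossval_compare(tr$X, specs, eta = 0.2, missing_fraction = 0.2,
                         n_reps = 3, seed = 88)
  paths <- write_crossval_report(cv, file.path(tempdir(), "cvtest"))
  expect_true(all(file.exists(paths)))
  tab <- utils::read.csv(paths[1])
  expect_equal(nrow(tab), 6L)
  expect_named(tab, c("replicate", "model", "tcs"))
})
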