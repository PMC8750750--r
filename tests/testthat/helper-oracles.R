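# Independent oracles and fixture builders shared across test files.

# O(IJKR) triple-loop CP reconstruction, independent of the package's
# unfolding-based implementation.
brute_force_reconstruct <- function(weights, A, B, C) {
  I <- nrow(A); J <- nrow(B); K <- nrow(C); R <- length(weights)
  X <- array(0, dim = c(I, J, K))
  for (i in seq_len(I)) for (j in seq_len(J)) for (k in seq_len(K))
    for (r in seq_len(R))
      X[i, j, k] <- X[i, j, k] + weights[r] * A[i, r] * B[j, r] * C[k, r]
  X
}

# A well-separated planted rank-2 model (unit-norm factors, distinct
# weights); time factors non-negative so the default constraints can
# recover it.
planted_rank2 <- function(I = 12, J = 8, K = 10, seed = 404) {
  set.seed(seed)
  normalize <- function(v) v / sqrt(sum(v^2))
  A <- cbind(normalize(rnorm(I)), normalize(rnorm(I)))
  B <- cbind(normalize(rnorm(J)), normalize(rnorm(J)))
  C <- cbind(normalize(abs(rnorm(K)) + 0.5), normalize(abs(rnorm(K)) + 0.1))
  # re-orthogonalize a little so components are well separated
  A[, 2] <- normalize(A[, 2] - sum(A[, 1] * A[, 2]) * A[, 1])
  B[, 2] <- normalize(B[, 2] - sum(B[, 1] * B[, 2]) * B[, 1])
  weights <- c(3, 1.5)
  list(weights = weights, A = A, B = B, C = C,
       X = brute_force_reconstruct(weights, A, B, C))
}

# Greedy component matching by absolute subject-mode congruence, then the
# per-component triple-product congruence after optimal sign alignment.
matched_congruences <- function(model, truth) {
  R <- length(truth$weights)
  used <- integer(0)
  out <- numeric(R)
  for (r in seq_len(R)) {
    cands <- setdiff(seq_len(R), used)
    scores <- vapply(cands, function(s) {
      abs(sum(model$A[, s] * truth$A[, r])) *
        abs(sum(model$B[, s] * truth$B[, r])) *
        abs(sum(model$C[, s] * truth$C[, r]))
    }, numeric(1))
    s <- cands[which.max(scores)]
    used <- c(used, s)
    out[r] <- max(scores)
  }
  out
}

small_random_tensor <- function(I = 8, J = 6, K = 7, seed = 99) {
  set.seed(seed)
  array(rnorm(I * J * K), dim = c(I, J, K))
}

# Cheap fitting options for unit tests on small fixtures.
quick_opts <- function(R, n_starts = 4L, seed = 1L, max_iters = 500L,
                       tol = 1e-9) {
  fit_options(n_components = R, n_starts = n_starts, max_iters = max_iters,
              tol = tol, seed = seed)
}
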