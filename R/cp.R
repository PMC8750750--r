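#' Options for CP / Paralind model fitting
#'
#' @param n_components number of components R (>= 1).
#' @param n_starts number of random initializations; the start with the
#'   lowest final objective is kept (ties broken by start index).
#' @param max_iters maximum alternating iterations per start.
#' @param tol relative objective-change stopping threshold.
#' @param nonneg_modes integer vector of modes constrained to be
#'   non-negative; defaults to the time mode (3).
#' @param seed integer seed; start s uses a stream derived from
#'   \code{(seed, s)}, so fits are deterministic given the seed.
#' @return an object of class \code{fit_options}.
#' @export
fit_options <- function(n_components = 2L, n_starts = 20L, max_iters = 1e4L,
                        tol = 1e-10, nonneg_modes = 3L, seed = 1L) {
  stopifnot(n_components >= 1L, n_starts >= 1L, max_iters >= 1L, tol > 0)
  structure(list(n_components = as.integer(n_components),
                 n_starts = as.integer(n_starts),
                 max_iters = as.integer(max_iters),
                 tol = tol,
                 nonneg_modes = as.integer(nonneg_modes),
                 seed = as.integer(seed)),
            class = "fit_options")
}

#' Reconstruct a tensor from a CP (or Paralind) decomposition
#'
#' Computes the sum of rank-one tensors sum_r lambda_r a_r o b_r o c_r.
#' For a Paralind model the effective subject factor A H is used.
#'
#' @param model a \code{cp_model} or \code{paralind_model}.
#' @return an I x J x K array.
#' @export
reconstruct <- function(model) {
  A <- effective_subject_factor(model)
  B <- model$B; C <- model$C
  if (ncol(A) != length(model$weights) || ncol(B) != ncol(A) ||
      ncol(C) != ncol(A))
    stop("factor matrices are not conformable with the weights")
  X1 <- A %*% (model$weights * t(khatri_rao(C, B)))
  fold(X1, 1L, c(nrow(A), nrow(B), nrow(C)))
}

effective_subject_factor <- function(model) {
  if (!is.null(model$H)) model$A %*% model$H else model$A
}

#' Explained fit of a tensor model (percent)
#'
#' Fit = 100 * (1 - ||X - Xhat||^2 / ||X||^2).  With a mask both norms are
#' restricted to observed entries.
#'
#' @param X data array (or [metabolomics_tensor()]).
#' @param X_hat model reconstruction, same shape.
#' @param mask optional binary observation array.
#' @return fit percentage (<= 100).
#' @export
fit_percent <- function(X, X_hat, mask = NULL) {
  mask <- tensor_mask(X, mask)
  V <- tensor_values(X)
  H <- tensor_values(X_hat)
  if (!identical(dim(V), dim(H))) stop("X and X_hat shapes differ")
  if (is.null(mask)) {
    den <- sum(V^2)
    num <- sum((V - H)^2)
  } else {
    den <- sum(mask * V^2)
    num <- sum(mask * (V - H)^2)
  }
  if (den == 0) stop("||X|| is zero; fit undefined")
  100 * (1 - num / den)
}

#' Fit a CP model by constrained alternating least squares
#'
#' Minimizes ||W * (X - [[lambda; A, B, C]])||^2 over the factor matrices,
#' where W is the observation mask (all ones when absent).  Each mode update
#' solves the exact least-squares subproblem via the Khatri-Rao normal
#' equations; modes listed in \code{opts$nonneg_modes} (the time mode by
#' default) are updated row-wise by non-negative least squares.  Missing
#' entries are handled by expectation-maximization: they are imputed from
#' the current model before each sweep, which monotonically decreases the
#' weighted objective.  The best of \code{opts$n_starts} random starts is
#' returned, normalized (unit-norm factor columns, norms absorbed into
#' lambda >= 0) and ordered by descending lambda, with component signs fixed
#' so each metabolites-mode column has a non-negative sum.
#'
#' @param X data array or [metabolomics_tensor()] (preprocessed, typically).
#' @param opts a [fit_options()].
#' @param mask optional binary observation array.
#' @return an object of class \code{cp_model}: \code{weights}, \code{A},
#'   \code{B}, \code{C}, \code{fit} (percent, on observed entries),
#'   \code{objective}, \code{n_iters}, \code{converged}, \code{trace}
#'   (objective per iteration of the winning start), \code{opts}.
#' @export
fit_cp <- function(X, opts = fit_options(), mask = NULL) {
  mask <- tensor_mask(X, mask)
  V <- tensor_values(X)
  if (any(!is.finite(V[if (is.null(mask)) TRUE else mask == 1])))
    stop("X contains non-finite values at observed entries")
  best <- NULL
  for (s in seq_len(opts$n_starts)) {
    set.seed(derive_seed(opts$seed, 97L, s))
    init <- random_init(dim(V), opts$n_components, opts$nonneg_modes)
    run <- tryCatch(
      als_cp(V, init, mask, opts),
      error = function(e) NULL)
    if (is.null(run)) next
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  if (is.null(best)) stop("all CP starts failed to converge")
  model <- normalize_cp(list(weights = rep(1, opts$n_components),
                             A = best$A, B = best$B, C = best$C))
  model$objective <- best$objective
  model$n_iters <- best$n_iters
  model$converged <- best$converged
  model$trace <- best$trace
  model$fit <- fit_percent(V, reconstruct(model), mask)
  model$opts <- opts
  class(model) <- "cp_model"
  model
}

#' @export
print.cp_model <- function(x, ...) {
  cat("<cp_model> R = ", length(x$weights), ", fit = ",
      sprintf("%.2f%%", x$fit), ", lambda = ",
      paste(signif(x$weights, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

random_init <- function(dims, R, nonneg_modes) {
  fac <- lapply(1:3, function(m) {
    F <- matrix(stats::rnorm(dims[m] * R), dims[m], R)
    if (m %in% nonneg_modes) F <- abs(F)
    F
  })
  names(fac) <- c("A", "B", "C")
  fac
}

# One full ALS run from a given initialization.  Missing entries (mask 0)
# are imputed from the current model at the top of every sweep (EM).  In
# the unmasked path the objective is evaluated from the factor Gram
# matrices (||X||^2 - 2<X3 Z3, C> + sum(C'C * (A'A o B'B))), avoiding a
# full reconstruction per iteration.
als_cp <- function(V, init, mask, opts) {
  dims <- dim(V)
  A <- init$A; B <- init$B; C <- init$C
  has_mask <- !is.null(mask)
  if (has_mask) miss <- which(mask == 0)
  Xw <- V
  if (has_mask) Xw[miss] <- 0   # first sweep: impute with zeros
  X1 <- unfold(Xw, 1L); X2 <- unfold(Xw, 2L); X3 <- unfold(Xw, 3L)
  normX2 <- if (has_mask) sum(mask * V^2) else sum(V^2)
  obj_prev <- Inf
  trace <- numeric(opts$max_iters)
  converged <- FALSE
  it <- 0L
  while (it < opts$max_iters) {
    it <- it + 1L
    if (has_mask && it > 1L) {
      Xh <- fold(A %*% t(khatri_rao(C, B)), 1L, dims)
      Xw <- V
      Xw[miss] <- Xh[miss]
      X1 <- unfold(Xw, 1L); X2 <- unfold(Xw, 2L); X3 <- unfold(Xw, 3L)
    }
    A <- update_mode(X1, B, C, nonneg = 1L %in% opts$nonneg_modes)
    B <- update_mode(X2, A, C, nonneg = 2L %in% opts$nonneg_modes)
    up <- update_mode(X3, A, B, nonneg = 3L %in% opts$nonneg_modes,
                      keep_parts = !has_mask)
    if (has_mask) {
      C <- up
      Xh <- fold(A %*% t(khatri_rao(C, B)), 1L, dims)
      obj <- sum(mask * (V - Xh)^2)
    } else {
      C <- up$F
      obj <- normX2 - 2 * sum(C * up$XtZ) +
        sum(crossprod(C) * (crossprod(A) * crossprod(B)))
      obj <- max(obj, 0)
    }
    trace[it] <- obj
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= opts$tol * max(obj_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  list(A = A, B = B, C = C, objective = trace[it],
       n_iters = it, converged = converged, trace = trace[seq_len(it)])
}

# Exact LS update of one mode: X_(n) ~ F * t(khatri_rao(P2, P1)).  The
# normal equations use the Hadamard-of-Gram identity; non-negative modes
# fall back to row-wise NNLS only for rows whose unconstrained solution is
# infeasible (time factors are mostly positive, so this path is rare).
update_mode <- function(Xn, P1, P2, nonneg = FALSE, keep_parts = FALSE) {
  Z <- khatri_rao(P2, P1)
  G <- crossprod(P2) * crossprod(P1)
  XtZ <- Xn %*% Z
  F <- tryCatch(t(solve(G, t(XtZ))),
                error = function(e) XtZ %*% pinv_sym(G))
  if (nonneg) {
    bad <- which(rowSums(F < -1e-12) > 0L)
    for (i in bad)
      F[i, ] <- pracma::lsqnonneg(Z, Xn[i, ])$x
    F[F < 0] <- 0
  }
  if (keep_parts) list(F = F, XtZ = XtZ) else F
}

# Moore-Penrose pseudoinverse of a small symmetric Gram matrix.
pinv_sym <- function(G, tol = 1e-12) {
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) stop("Gram matrix is numerically zero")
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

# Normalize factor columns to unit 2-norm, absorb norms (and signs) into
# lambda, enforce lambda >= 0 and non-negative metabolites-mode column sums,
# and order components by descending lambda.
normalize_cp <- function(model) {
  A <- model$A; B <- model$B; C <- model$C
  R <- ncol(A)
  lambda <- model$weights
  for (r in seq_len(R)) {
    for (F in c("A", "B", "C")) {
      col <- get(F)[, r]
      nr <- sqrt(sum(col^2))
      if (nr == 0) stop("component ", r, " collapsed to zero in mode ", F)
      assign(F, `[<-`(get(F), , r, value = col / nr))
      lambda[r] <- lambda[r] * nr
    }
    if (lambda[r] < 0) {         # flip subject column, keep lambda >= 0
      lambda[r] <- -lambda[r]
      A[, r] <- -A[, r]
    }
    if (sum(B[, r]) < 0) {       # fix reflection: flip B and A together
      B[, r] <- -B[, r]
      A[, r] <- -A[, r]
    }
  }
  ord <- order(lambda, decreasing = TRUE)
  list(weights = lambda[ord], A = A[, ord, drop = FALSE],
       B = B[, ord, drop = FALSE], C = C[, ord, drop = FALSE])
}

#' Write fitted factor matrices to delimited text
#'
#' Emits \code{<stem>_subjects.csv}, \code{<stem>_metabolites.csv},
#' \code{<stem>_time.csv} (factors with mode labels as row names),
#' \code{<stem>_lambda.csv}, for Paralind additionally \code{<stem>_H.csv},
#' and a \code{<stem>_manifest.csv} recording R, constraints, seed,
#' number of starts and final objective.
#'
#' @param model a \code{cp_model} or \code{paralind_model}.
#' @param stem output path stem.
#' @param mode_labels optional list with elements \code{subjects},
#'   \code{metabolites}, \code{time} used as row names.
#' @return invisibly, the paths written.
#' @export
write_factors <- function(model, stem, mode_labels = NULL) {
  paths <- character(0)
  emit <- function(M, what, labels = NULL) {
    df <- as.data.frame(M)
    names(df) <- paste0("comp", seq_len(ncol(M)))
    if (!is.null(labels)) rownames(df) <- labels
    p <- paste0(stem, "_", what, ".csv")
    utils::write.csv(df, p, row.names = !is.null(labels))
    paths <<- c(paths, p)
  }
  emit(effective_subject_factor(model), "subjects", mode_labels$subjects)
  emit(model$B, "metabolites", mode_labels$metabolites)
  emit(model$C, "time", mode_labels$time)
  emit(matrix(model$weights, nrow = 1), "lambda")
  if (!is.null(model$H)) emit(model$H, "H")
  manifest <- data.frame(
    kind = if (!is.null(model$H)) "paralind" else "cp",
    R = length(model$weights),
    S = if (!is.null(model$H)) nrow(model$H) else NA_integer_,
    nonneg_modes = paste(model$opts$nonneg_modes, collapse = ";"),
    seed = model$opts$seed,
    n_starts = model$opts$n_starts,
    objective = model$objective,
    fit = model$fit)
  p <- paste0(stem, "_manifest.csv")
  utils::write.csv(manifest, p, row.names = FALSE)
  invisible(c(paths, p))
}
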