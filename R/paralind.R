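#' Build a Paralind dependency matrix from a grouping pattern
#'
#' Paralind(S, R, R) expresses the subject-mode factor as A H where A has
#' only S independent columns and the binary S x R dependency matrix H
#' records which components share which column.  With each of the R
#' components assigned to exactly one of the S basis vectors, H has entry 1
#' at (s, r) when component r uses basis s.  For example, a 3-component
#' model whose first two components share one subject profile has
#' \code{dependency_matrix(2, 3, c(1, 1, 2))} = rbind(c(1,1,0), c(0,0,1)).
#'
#' @param S number of independent subject-mode columns (<= R).
#' @param R number of components.
#' @param groups length-R integer vector in 1..S assigning each component
#'   to a basis column; every basis must be used by at least one component.
#' @return a binary S x R matrix.
#' @export
dependency_matrix <- function(S, R, groups) {
  stopifnot(S >= 1L, R >= S, length(groups) == R)
  groups <- as.integer(groups)
  if (any(groups < 1L | groups > S))
    stop("`groups` entries must lie in 1..S")
  if (length(unique(groups)) < S)
    stop("every basis column must be used by at least one component ",
         "(empty basis group)")
  H <- matrix(0, S, R)
  H[cbind(groups, seq_len(R))] <- 1
  H
}

#' Fit a Paralind(S, R, R) model
#'
#' Minimizes ||W * (X - [[lambda; A H, B, C]])||^2 by constrained
#' alternating least squares: the I x S basis factor A is updated by exact
#' least squares through the dependency matrix H; the metabolites factor B
#' is constrained to have orthonormal columns and is updated by the
#' orthogonal-Procrustes solution of its subproblem; the time factor C is
#' updated row-wise by non-negative least squares.  Missing entries are
#' handled by EM imputation as in [fit_cp()], and the best of
#' \code{opts$n_starts} random starts is kept.
#'
#' The returned model is normalized: B orthonormal, C columns unit norm,
#' A columns unit norm (so the effective subject columns of A H are unit
#' norm for a single-membership H), all norms absorbed into lambda >= 0.
#' Only the product A H is identified; A and H individually are not.
#'
#' @param X data array or [metabolomics_tensor()].
#' @param S number of independent subject-mode columns.
#' @param R number of components.
#' @param H dependency matrix; defaults to
#'   \code{dependency_matrix(S, R, groups)}.
#' @param groups grouping pattern used when \code{H} is NULL; defaults to
#'   components 1..S mapping to bases 1..S and the remainder to basis S.
#' @param opts a [fit_options()] (\code{n_components} is taken from
#'   \code{R}).
#' @param mask optional binary observation array.
#' @param orthogonal_metabolites impose orthonormal columns on B
#'   (default TRUE, the constraint set that makes the model unique).
#' @return an object of class \code{paralind_model} with \code{weights},
#'   \code{A} (I x S), \code{H}, \code{B}, \code{C}, \code{fit},
#'   \code{objective}, \code{n_iters}, \code{converged}, \code{trace},
#'   \code{opts}.
#' @export
fit_paralind <- function(X, S, R, H = NULL, groups = NULL,
                         opts = fit_options(n_components = R),
                         mask = NULL, orthogonal_metabolites = TRUE) {
  stopifnot(S >= 1L, R >= S)
  if (is.null(H)) {
    if (is.null(groups)) groups <- pmin(seq_len(R), S)
    H <- dependency_matrix(S, R, groups)
  }
  stopifnot(nrow(H) == S, ncol(H) == R)
  mask <- tensor_mask(X, mask)
  V <- tensor_values(X)
  if (any(!is.finite(V[if (is.null(mask)) TRUE else mask == 1])))
    stop("X contains non-finite values at observed entries")
  opts$n_components <- as.integer(R)
  best <- NULL
  for (s in seq_len(opts$n_starts)) {
    set.seed(derive_seed(opts$seed, 193L, s))
    A <- matrix(stats::rnorm(dim(V)[1] * S), dim(V)[1], S)
    B <- qr.Q(qr(matrix(stats::rnorm(dim(V)[2] * R), dim(V)[2], R)))
    C <- abs(matrix(stats::rnorm(dim(V)[3] * R), dim(V)[3], R))
    run <- tryCatch(
      als_paralind(V, A, H, B, C, mask, opts, orthogonal_metabolites),
      error = function(e) NULL)
    if (is.null(run)) next
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  if (is.null(best)) stop("all Paralind starts failed to converge")
  model <- normalize_paralind(best$A, H, best$B, best$C)
  model$objective <- best$objective
  model$n_iters <- best$n_iters
  model$converged <- best$converged
  model$trace <- best$trace
  model$fit <- fit_percent(V, reconstruct(model), mask)
  model$opts <- opts
  class(model) <- "paralind_model"
  model
}

#' @export
print.paralind_model <- function(x, ...) {
  cat("<paralind_model> Paralind(", nrow(x$H), ",", ncol(x$H), ",",
      ncol(x$H), "), fit = ", sprintf("%.2f%%", x$fit), "\n", sep = "")
  invisible(x)
}

als_paralind <- function(V, A, H, B, C, mask, opts, ortho_B) {
  dims <- dim(V)
  has_mask <- !is.null(mask)
  if (has_mask) miss <- which(mask == 0)
  Xw <- V
  if (has_mask) Xw[miss] <- 0
  X1 <- unfold(Xw, 1L); X2 <- unfold(Xw, 2L); X3 <- unfold(Xw, 3L)
  normX2 <- if (has_mask) sum(mask * V^2) else sum(V^2)
  obj_prev <- Inf
  trace <- numeric(opts$max_iters)
  converged <- FALSE
  it <- 0L
  while (it < opts$max_iters) {
    it <- it + 1L
    At <- A %*% H
    if (has_mask && it > 1L) {
      Xh <- fold(At %*% t(khatri_rao(C, B)), 1L, dims)
      Xw <- V
      Xw[miss] <- Xh[miss]
      X1 <- unfold(Xw, 1L); X2 <- unfold(Xw, 2L); X3 <- unfold(Xw, 3L)
    }
    # A-update: X1 ~ A [H t(KR(C, B))], exact LS in the reduced basis
    ZH <- khatri_rao(C, B) %*% t(H)
    G <- crossprod(ZH)
    XtZ <- X1 %*% ZH
    A <- tryCatch(t(solve(G, t(XtZ))), error = function(e) XtZ %*% pinv_sym(G))
    At <- A %*% H
    # B-update: orthogonal Procrustes on X2 ~ B t(KR(C, At))
    if (ortho_B) {
      M <- X2 %*% khatri_rao(C, At)
      if (fnorm(M) > 0) {            # zero residual matrix: keep previous B
        sv <- svd(M)
        B <- sv$u %*% t(sv$v)
      }
    } else {
      B <- update_mode(X2, At, C, nonneg = FALSE)
    }
    # C-update: row-wise NNLS on X3 ~ C t(KR(B, At))
    up <- update_mode(X3, At, B, nonneg = 3L %in% opts$nonneg_modes,
                      keep_parts = !has_mask)
    if (has_mask) {
      C <- up
      Xh <- fold(At %*% t(khatri_rao(C, B)), 1L, dims)
      obj <- sum(mask * (V - Xh)^2)
    } else {
      C <- up$F
      obj <- normX2 - 2 * sum(C * up$XtZ) +
        sum(crossprod(C) * (crossprod(At) * crossprod(B)))
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

# Normalization: per-component norms of A H (via A columns), B, C absorbed
# into lambda; lambda made non-negative by flipping B columns (B stays
# orthogonal up to column signs); components ordered by descending lambda
# with H permuted in step.
normalize_paralind <- function(A, H, B, C) {
  S <- ncol(A); R <- ncol(B)
  lambda <- rep(1, R)
  nz_per_col <- colSums(H != 0)
  if (any(nz_per_col != 1L))
    stop("normalization assumes a single-membership dependency matrix ",
         "(exactly one nonzero per column of H)")
  basis_of <- apply(H, 2L, function(h) which(h != 0))
  for (s in seq_len(S)) {
    nr <- sqrt(sum(A[, s]^2))
    if (nr == 0) stop("basis column ", s, " collapsed to zero")
    A[, s] <- A[, s] / nr
    comps <- which(basis_of == s)
    lambda[comps] <- lambda[comps] * nr * H[s, comps]
    H[s, comps] <- 1
  }
  for (r in seq_len(R)) {
    for (F in c("B", "C")) {
      col <- get(F)[, r]
      nr <- sqrt(sum(col^2))
      if (nr == 0) stop("component ", r, " collapsed to zero in mode ", F)
      assign(F, `[<-`(get(F), , r, value = col / nr))
      lambda[r] <- lambda[r] * nr
    }
    if (lambda[r] < 0) {
      lambda[r] <- -lambda[r]
      B[, r] <- -B[, r]
    }
  }
  ord <- order(lambda, decreasing = TRUE)
  list(weights = lambda[ord], A = A, H = H[, ord, drop = FALSE],
       B = B[, ord, drop = FALSE], C = C[, ord, drop = FALSE])
}
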