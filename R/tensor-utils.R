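#' Mode-n matricization of a three-way array
#'
#' Unfolds an \code{I x J x K} array along one mode using the standard
#' (Kolda--Bader) column ordering, so that the mode-1 unfolding satisfies
#' \code{X1 = A \%*\% t(khatri_rao(C, B))} for a CP model with factors
#' \code{A, B, C}.
#'
#' @param X a three-dimensional numeric array.
#' @param mode the mode to unfold along (1, 2 or 3).
#' @return a matrix with \code{dim(X)[mode]} rows.
#' @keywords internal
unfold <- function(X, mode) {
  stopifnot(length(dim(X)) == 3L)
  d <- dim(X)
  switch(as.character(mode),
    "1" = matrix(X, d[1], d[2] * d[3]),
    "2" = matrix(aperm(X, c(2L, 1L, 3L)), d[2], d[1] * d[3]),
    "3" = matrix(aperm(X, c(3L, 1L, 2L)), d[3], d[1] * d[2]),
    stop("`mode` must be 1, 2 or 3"))
}

#' Inverse of [unfold()]
#'
#' @param M a matricized tensor.
#' @param mode the mode `M` was unfolded along.
#' @param dims the dimensions of the original array.
#' @return a three-dimensional array.
#' @keywords internal
fold <- function(M, mode, dims) {
  switch(as.character(mode),
    "1" = array(M, dims),
    "2" = aperm(array(M, dims[c(2L, 1L, 3L)]), c(2L, 1L, 3L)),
    "3" = aperm(array(M, dims[c(3L, 1L, 2L)]), c(2L, 3L, 1L)),
    stop("`mode` must be 1, 2 or 3"))
}

#' Column-wise Khatri-Rao (matching-columnwise Kronecker) product
#'
#' @param P,Q matrices with the same number of columns.
#' @return a matrix with \code{nrow(P) * nrow(Q)} rows; column r is
#'   \code{kronecker(P[, r], Q[, r])}.
#' @keywords internal
khatri_rao <- function(P, Q) {
  stopifnot(ncol(P) == ncol(Q))
  P[rep(seq_len(nrow(P)), each = nrow(Q)), , drop = FALSE] *
    Q[rep(seq_len(nrow(Q)), times = nrow(P)), , drop = FALSE]
}

#' Frobenius norm of an array or matrix
#' @param X numeric array.
#' @keywords internal
fnorm <- function(X) sqrt(sum(X^2))

# Deterministic derivation of a child RNG seed from a root seed and stream
# indices.  Kept below 2^31 - 1 so it is always a valid R integer seed.
# Streams indexed by (i, j) are independent of how many other streams exist,
# so e.g. adding a cohort group never changes earlier subjects' draws.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 1009 + as.double(i) * 100003 +
                as.double(j) * 7919) %% 2147483629)
}

# Extract the numeric array (and optional mask) from either a plain array or
# a metabolomics_tensor.
tensor_values <- function(X) {
  if (inherits(X, "metabolomics_tensor")) X$values else X
}

tensor_mask <- function(X, mask = NULL) {
  if (!is.null(mask)) return(mask)
  if (inherits(X, "metabolomics_tensor")) X$mask else NULL
}
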