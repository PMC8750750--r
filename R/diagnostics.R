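#' Core consistency diagnostic
#'
#' Measures how superdiagonal the least-squares Tucker core is when the data
#' are projected onto the fitted CP factors.  With lambda folded into the
#' subject factor, the ideal core is the R x R x R superdiagonal array of
#' ones T; the diagnostic is CC = 100 * (1 - sum((G - T)^2) / sum(T^2)) with
#' sum(T^2) = R (the corcond normalization).  Values near 100 indicate an
#' appropriate number of components; values that collapse towards (or below)
#' zero indicate too many.
#'
#' @param X data array or [metabolomics_tensor()] the model was fitted to.
#' @param model a \code{cp_model}.
#' @return core consistency percentage (<= 100).
#' @export
core_consistency <- function(X, model) {
  V <- tensor_values(X)
  R <- length(model$weights)
  A <- effective_subject_factor(model) %*% diag(model$weights, R)
  B <- model$B; C <- model$C
  if (R > min(dim(V)))
    stop("core solve ill-posed: R exceeds the smallest tensor dimension")
  K3 <- kronecker(C, kronecker(B, A))       # IJK x R^3, vec(X) = K3 vec(G)
  G <- crossprod(K3)
  if (rcond(G) < 1e-12)
    stop("rank-deficient factor matrices; core solve ill-posed")
  g <- solve(G, crossprod(K3, as.vector(V)))
  target <- as.vector(array_superdiag(R))
  100 * (1 - sum((g - target)^2) / R)
}

array_superdiag <- function(R) {
  T <- array(0, dim = c(R, R, R))
  for (r in seq_len(R)) T[r, r, r] <- 1
  T
}

#' Cosine similarity of two vectors
#'
#' @param u,v nonzero numeric vectors of equal length.
#' @return scalar in [-1, 1].
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

#' Tucker congruence matrix of a fitted model
#'
#' TC[i, j] is the product over the three modes of the cosine similarities
#' of components i and j; TC is symmetric with unit diagonal.  An
#' off-diagonal value near -1 flags two-factor degeneracy (two components
#' with nearly opposite, cancelling contributions).
#'
#' @param model a \code{cp_model} or \code{paralind_model}.
#' @return an R x R matrix.
#' @export
congruence_matrix <- function(model) {
  A <- effective_subject_factor(model)
  R <- ncol(A)
  TC <- matrix(1, R, R)
  if (R >= 2) {
    for (i in 1:(R - 1)) for (j in (i + 1):R) {
      TC[i, j] <- TC[j, i] <-
        cosine_similarity(A[, i], A[, j]) *
        cosine_similarity(model$B[, i], model$B[, j]) *
        cosine_similarity(model$C[, i], model$C[, j])
    }
  }
  TC
}

#' Scalar Tucker congruence (degeneracy indicator)
#'
#' Returns the signed off-diagonal congruence of largest magnitude, the
#' index pair attaining it, and a degeneracy flag raised when TC < -0.85
#' (a fitted model with congruence close to -1 is degenerate and not a
#' valid solution; the -0.85 cut-off is this package's reporting
#' convention).
#'
#' @param model a \code{cp_model} or \code{paralind_model}.
#' @return list with \code{tc}, \code{pair} (i, j), \code{degenerate}.
#' @export
tucker_congruence <- function(model) {
  TC <- congruence_matrix(model)
  R <- ncol(TC)
  if (R < 2) return(list(tc = NA_real_, pair = c(NA, NA), degenerate = FALSE))
  off <- abs(TC); diag(off) <- -Inf
  idx <- which(off == max(off), arr.ind = TRUE)[1, ]
  tc <- TC[idx[1], idx[2]]
  list(tc = tc, pair = unname(sort(idx)), degenerate = tc < -0.85)
}

#' Tensor completion score (held-out reconstruction error)
#'
#' TCS = ||(1 - W) * (Xhat - X)|| / ||(1 - W) * X||: the relative Frobenius
#' error of a reconstruction restricted to the entries deliberately held
#' out by the mask W.  Lower is better; the score ignores observed entries
#' entirely.
#'
#' @param X the (noisy) data the mask was applied to.
#' @param X_hat the model reconstruction.
#' @param W binary observation mask (0 = held out); must hold out at least
#'   one entry with nonzero data norm.
#' @return non-negative scalar.
#' @export
tcs <- function(X, X_hat, W) {
  V <- tensor_values(X); Hh <- tensor_values(X_hat)
  stopifnot(identical(dim(V), dim(Hh)), identical(dim(W), dim(V)))
  miss <- W == 0
  if (!any(miss)) stop("mask holds out no entries; TCS undefined")
  den <- sqrt(sum(V[miss]^2))
  if (den == 0) stop("held-out entries have zero norm; TCS undefined")
  sqrt(sum((Hh[miss] - V[miss])^2)) / den
}

#' Model specifications for cross-validation comparisons
#'
#' Lightweight descriptors naming the model to fit in each replicate of
#' [crossval_compare()] or [fit_model()].
#'
#' @param R number of components.
#' @param S number of independent subject-mode columns (Paralind).
#' @param groups Paralind grouping pattern (see [dependency_matrix()]).
#' @param n_starts,max_iters,tol,seed fitting controls, see [fit_options()].
#' @param label display label; defaults to e.g. "CP(R=2)" or
#'   "Paralind(1,2,2)".
#' @return an object of class \code{model_spec}.
#' @export
cp_spec <- function(R, n_starts = 20L, max_iters = 1e4L, tol = 1e-10,
                    seed = 1L, label = sprintf("CP(R=%d)", R)) {
  structure(list(kind = "cp", R = as.integer(R), S = NULL, groups = NULL,
                 n_starts = as.integer(n_starts),
                 max_iters = as.integer(max_iters), tol = tol,
                 seed = as.integer(seed), label = label),
            class = "model_spec")
}

#' @rdname cp_spec
#' @export
paralind_spec <- function(S, R, groups = NULL, n_starts = 20L,
                          max_iters = 1e4L, tol = 1e-10, seed = 1L,
                          label = sprintf("Paralind(%d,%d,%d)", S, R, R)) {
  structure(list(kind = "paralind", R = as.integer(R), S = as.integer(S),
                 groups = groups, n_starts = as.integer(n_starts),
                 max_iters = as.integer(max_iters), tol = tol,
                 seed = as.integer(seed), label = label),
            class = "model_spec")
}

#' Fit the model described by a model_spec
#'
#' @param X data array or [metabolomics_tensor()].
#' @param spec a [cp_spec()] or [paralind_spec()].
#' @param mask optional binary observation array.
#' @param seed overrides the spec's seed when given.
#' @return a \code{cp_model} or \code{paralind_model}.
#' @export
fit_model <- function(X, spec, mask = NULL, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  opts <- fit_options(n_components = spec$R, n_starts = spec$n_starts,
                      max_iters = spec$max_iters, tol = spec$tol,
                      seed = seed %||% spec$seed)
  if (spec$kind == "cp") {
    fit_cp(X, opts, mask = mask)
  } else {
    fit_paralind(X, S = spec$S, R = spec$R, groups = spec$groups,
                 opts = opts, mask = mask)
  }
}

#' Missing-data cross-validation comparison of tensor models
#'
#' Replicates the held-out-entry protocol: in each replicate, noise at
#' relative level eta is added to the raw tensor, one shared random mask
#' holds out \code{missing_fraction} of the entries, the masked noisy
#' tensor is preprocessed (statistics over observed entries only), every
#' candidate model is fitted with the mask, and the tensor completion score
#' is computed on the preprocessed scale.  Because all models see the same
#' mask in a replicate, the scores are paired; the first two models are
#' compared with a two-sided paired t-test.
#'
#' @param X raw (unpreprocessed) data array or [metabolomics_tensor()].
#' @param model_specs list of at least two [cp_spec()]/[paralind_spec()]
#'   objects.
#' @param eta relative noise level.
#' @param missing_fraction fraction of entries held out per replicate.
#' @param n_reps number of replicates.
#' @param seed root seed; each replicate uses a derived stream.
#' @return an object of class \code{crossval_report}: \code{tcs}
#'   (n_reps x n_models matrix with model labels), \code{tcs_long}
#'   (data.frame replicate/model/tcs), \code{paired_p}, \code{medians}.
#' @export
crossval_compare <- function(X, model_specs, eta = 0.3,
                             missing_fraction = 0.2, n_reps = 20L,
                             seed = 1L) {
  stopifnot(length(model_specs) >= 2L)
  labels <- vapply(model_specs, `[[`, character(1), "label")
  V <- tensor_values(X)
  scores <- matrix(NA_real_, n_reps, length(model_specs),
                   dimnames = list(NULL, labels))
  for (rep in seq_len(n_reps)) {
    set.seed(derive_seed(seed, 331L, rep))
    Xn <- add_noise(V, eta)
    W <- make_missing_mask(dim(V), missing_fraction)
    pp <- preprocess_tensor(Xn, W)
    for (m in seq_along(model_specs)) {
      fit <- tryCatch(
        fit_model(pp$values, model_specs[[m]], mask = W,
                  seed = derive_seed(seed, 733L + m, rep)),
        error = function(e) {
          warning("replicate ", rep, ", model '", labels[m],
                  "' failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(fit)) next
      scores[rep, m] <- tcs(pp$values, reconstruct(fit), W)
    }
  }
  if (anyNA(scores))
    stop("not all replicates completed for every model; see warnings")
  pt <- stats::t.test(scores[, 1], scores[, 2], paired = TRUE)
  structure(list(
    tcs = scores,
    tcs_long = data.frame(replicate = rep(seq_len(n_reps), ncol(scores)),
                          model = rep(labels, each = n_reps),
                          tcs = as.vector(scores)),
    paired_p = pt$p.value,
    medians = apply(scores, 2L, stats::median)),
    class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("<crossval_report> ", nrow(x$tcs), " replicates\n", sep = "")
  cat("  median TCS: ",
      paste(sprintf("%s = %.4f", colnames(x$tcs), x$medians),
            collapse = ", "), "\n", sep = "")
  cat("  paired t-test (first two models): p = ",
      format.pval(x$paired_p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write a cross-validation report to disk
#'
#' Emits \code{<stem>_tcs.csv} (columns replicate, model, TCS) and a JSON
#' summary \code{<stem>_report.json} with medians and the paired p-value.
#'
#' @param report a \code{crossval_report}.
#' @param stem output path stem.
#' @return invisibly, the paths written.
#' @export
write_crossval_report <- function(report, stem) {
  stopifnot(inherits(report, "crossval_report"))
  p1 <- paste0(stem, "_tcs.csv")
  utils::write.csv(report$tcs_long, p1, row.names = FALSE)
  p2 <- paste0(stem, "_report.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(medians = as.list(report$medians),
                              paired_p = report$paired_p),
                         p2, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(sprintf('{"paired_p": %.10g}', report$paired_p), p2)
  }
  invisible(c(p1, p2))
}
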