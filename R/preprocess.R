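#' Center a tensor across the subjects mode
#'
#' For every (metabolite, time) fiber, subtracts the mean over observed
#' subjects, removing the common trajectory so that the analysis focuses on
#' between-subject variation.  With a mask, means are computed over observed
#' entries only but the subtraction is applied to all entries (so held-out
#' entries live on the same centered scale).
#'
#' @param X numeric I x J x K array or [metabolomics_tensor()].
#' @param mask optional binary observation array (defaults to the tensor's
#'   own mask, if any).
#' @return list with \code{values} (centered array) and \code{offsets}
#'   (J x K matrix of removed means).
#' @export
center_across_subjects <- function(X, mask = NULL) {
  mask <- tensor_mask(X, mask)
  V <- tensor_values(X)
  d <- dim(V)
  if (is.null(mask)) {
    offsets <- apply(V, c(2, 3), mean)
  } else {
    cnt <- apply(mask, c(2, 3), sum)
    if (any(cnt == 0)) {
      bad <- which(cnt == 0, arr.ind = TRUE)[1, ]
      stop("fiber (metabolite ", bad[1], ", time ", bad[2],
           ") has no observed entries; cannot center")
    }
    offsets <- apply(V * mask, c(2, 3), sum) / cnt
  }
  centered <- V - aperm(array(offsets, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  list(values = centered, offsets = offsets)
}

#' Scale a tensor within the metabolites mode
#'
#' Divides each metabolite slice (I x K) by its root-mean-square over
#' observed entries, putting metabolites with different concentration ranges
#' on a comparable scale.  The RMS denominator is the count of observed
#' entries in the slice.
#'
#' @inheritParams center_across_subjects
#' @return list with \code{values} (scaled array) and \code{scales}
#'   (length-J vector of removed RMS values).
#' @export
scale_within_metabolites <- function(X, mask = NULL) {
  mask <- tensor_mask(X, mask)
  V <- tensor_values(X)
  J <- dim(V)[2]
  scales <- numeric(J)
  for (j in seq_len(J)) {
    slice <- V[, j, ]
    if (is.null(mask)) {
      scales[j] <- sqrt(mean(slice^2))
    } else {
      w <- mask[, j, ]
      n_obs <- sum(w)
      if (n_obs == 0)
        stop("metabolite slice ", j, " has no observed entries; cannot scale")
      scales[j] <- sqrt(sum(w * slice^2) / n_obs)
    }
    if (scales[j] == 0)
      stop("metabolite slice ", j, " has zero RMS; cannot scale")
    V[, j, ] <- slice / scales[j]
  }
  list(values = V, scales = scales)
}

#' Center then scale a tensor (standard preprocessing)
#'
#' Centers across the subjects mode, then scales within the metabolites
#' mode.  Because scaling multiplies whole metabolite slices by constants,
#' the centering is preserved: observed subject-means remain zero after both
#' steps, so a single pass suffices.
#'
#' @inheritParams center_across_subjects
#' @return list with \code{values} (preprocessed array; a
#'   [metabolomics_tensor()] in, same type out) and \code{state}, a
#'   \code{preprocess_state} holding \code{offsets} (J x K) and
#'   \code{scales} (length J) for inversion or reuse.
#' @export
preprocess_tensor <- function(X, mask = NULL) {
  mask <- tensor_mask(X, mask)
  cen <- center_across_subjects(X, mask)
  sca <- scale_within_metabolites(cen$values, mask)
  state <- structure(list(offsets = cen$offsets, scales = sca$scales),
                     class = "preprocess_state")
  out <- sca$values
  if (inherits(X, "metabolomics_tensor")) {
    X$values[] <- out
    X$mask <- mask
    out <- X
  }
  list(values = out, state = state)
}

#' Invert preprocessing
#'
#' Maps a tensor on the preprocessed scale back to the original scale:
#' multiplies metabolite slices by their stored RMS and adds back the stored
#' subject-mode means.
#'
#' @param X preprocessed array or [metabolomics_tensor()].
#' @param state a \code{preprocess_state} from [preprocess_tensor()].
#' @return array (or tensor) on the original scale.
#' @export
invert_preprocess <- function(X, state) {
  stopifnot(inherits(state, "preprocess_state"))
  V <- tensor_values(X)
  d <- dim(V)
  for (j in seq_len(d[2])) V[, j, ] <- V[, j, ] * state$scales[j]
  V <- V + aperm(array(state$offsets, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  if (inherits(X, "metabolomics_tensor")) {
    X$values[] <- V
    X
  } else V
}

#' Write preprocessing state to delimited text
#'
#' @param state a \code{preprocess_state}.
#' @param stem output path stem; writes \code{<stem>_offsets.csv} (J x K)
#'   and \code{<stem>_scales.csv} (J rows).
#' @return invisibly, the paths written.
#' @export
write_preprocess_state <- function(state, stem) {
  stopifnot(inherits(state, "preprocess_state"))
  p1 <- paste0(stem, "_offsets.csv")
  p2 <- paste0(stem, "_scales.csv")
  utils::write.csv(state$offsets, p1, row.names = FALSE)
  utils::write.csv(data.frame(scale = state$scales), p2, row.names = FALSE)
  invisible(c(p1, p2))
}
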