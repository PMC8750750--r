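#' The linear open system of 11 metabolites
#'
#' Constructs a linear metabolic network dx/dt = A x + b with a tridiagonal
#' rate matrix A (1/min), constant influx b (concentration/min) into the
#' first metabolite, and initial state x0.  Off-diagonal entries are
#' first-order exchange rates between neighbouring metabolites; the
#' diagonal of columns 1 to J-1 is closed so that each column sums to zero
#' (mass conservation within the chain), while the last diagonal entry is
#' fixed to a given efflux rate, making the system open.
#'
#' The default arguments give the 11-metabolite system used throughout the
#' package's experiments: b = 1e3 * (0.1, 0, ..., 0), subdiagonal
#' 1e3 * (0.2, 0.1, 0.5, 0.3, 2, 1, 3, 0.4, 1, 0.4), superdiagonal
#' 1e3 * (0.3, 0.5, 2, 2, 0.3, 3, 0.5, 1, 0.2, 0.4), A[11,11] = -1e3,
#' and x0 = (1, ..., 1).
#'
#' @param sub numeric vector of subdiagonal rates (length J - 1), strictly
#'   positive.
#' @param sup numeric vector of superdiagonal rates (length J - 1), strictly
#'   positive.
#' @param b influx vector (length J).
#' @param x0 initial state (length J).
#' @param diag_last the fixed last diagonal entry A[J,J] (net efflux).
#' @param diag optional explicit diagonal overriding the zero-column-sum
#'   closure (used by the degenerate-case variant); \code{diag_last} is
#'   ignored when given.
#' @param metabolite_names optional labels, default \code{M1..MJ}.
#' @return an object of class \code{linear_system} with elements
#'   \code{A, b, x0, sub, sup, diag_last, metabolite_names}.
#' @export
#' @examples
#' sys <- linear_system()
#' sys$A[2, 1]            # 200
#' colSums(sys$A)[1:10]   # all zero
linear_system <- function(sub = 1e3 * c(0.2, 0.1, 0.5, 0.3, 2, 1, 3, 0.4, 1, 0.4),
                          sup = 1e3 * c(0.3, 0.5, 2, 2, 0.3, 3, 0.5, 1, 0.2, 0.4),
                          b = 1e3 * c(0.1, rep(0, 10)),
                          x0 = rep(1, 11),
                          diag_last = -1e3,
                          diag = NULL,
                          metabolite_names = NULL) {
  J <- length(b)
  stopifnot(length(sub) == J - 1L, length(sup) == J - 1L, length(x0) == J)
  if (any(sub <= 0) || any(sup <= 0))
    stop("sub- and superdiagonal rates must be strictly positive")
  if (is.null(metabolite_names)) metabolite_names <- paste0("M", seq_len(J))
  if (!is.null(diag)) {
    stopifnot(length(diag) == J)
    diag_last <- diag[J]
  }
  sys <- structure(list(A = NULL, b = b, x0 = x0, sub = sub, sup = sup,
                        diag_last = diag_last, explicit_diag = diag,
                        metabolite_names = metabolite_names),
                   class = "linear_system")
  rebuild_matrix(sys)
}

# Rebuild A from sub/sup and the diagonal rule.  With no explicit diagonal,
# columns 1..J-1 are closed to zero sum and A[J,J] is pinned to diag_last;
# this is re-run after every parameter perturbation or knock-down so the
# mass-conservation constraint holds for every realized subject.
rebuild_matrix <- function(sys) {
  J <- length(sys$b)
  A <- matrix(0, J, J)
  A[cbind(2:J, 1:(J - 1))] <- sys$sub
  A[cbind(1:(J - 1), 2:J)] <- sys$sup
  if (is.null(sys$explicit_diag)) {
    for (j in 1:(J - 1)) A[j, j] <- -sum(A[-j, j])
    A[J, J] <- sys$diag_last
  } else {
    diag(A) <- sys$explicit_diag
  }
  dimnames(A) <- list(sys$metabolite_names, sys$metabolite_names)
  sys$A <- A
  sys
}

#' The degenerate-case variant of the linear open system
#'
#' A tridiagonal system with all off-diagonal rates equal to 1e3, diagonal
#' 1e3 * (-1, -2, ..., -2), and influx b = 1e3 * (0.5, 0, ..., 0).  At low
#' individual variation the 2-component CP model of cohorts from this system
#' exhibits two-factor degeneracy (Tucker congruence near -1), while the
#' Paralind model remains well behaved.
#'
#' @return a \code{linear_system}.
#' @export
degenerate_linear_system <- function() {
  linear_system(sub = rep(1e3, 10), sup = rep(1e3, 10),
                b = 1e3 * c(0.5, rep(0, 10)),
                diag = 1e3 * c(-1, rep(-2, 10)))
}

#' @export
print.linear_system <- function(x, ...) {
  cat("<linear_system> ", length(x$b), " metabolites, tridiagonal A",
      if (is.null(x$explicit_diag)) " (zero column sums)", "\n", sep = "")
  invisible(x)
}

#' @export
simulate_system.linear_system <- function(system, times, rtol = 1e-8,
                                          atol = 1e-10) {
  check_times(times)
  A <- system$A
  x_ss <- solve(A, -system$b)
  dev0 <- system$x0 - x_ss
  conc <- vapply(times, function(t) {
    if (t == 0) return(system$x0)
    as.numeric(x_ss + as.matrix(Matrix::expm(A * t)) %*% dev0)
  }, numeric(length(system$x0)))
  conc <- matrix(conc, nrow = length(system$x0))
  dimnames(conc) <- list(system$metabolite_names, signif(times, 8))
  conc
}

#' @export
steady_state.linear_system <- function(system, t_max = 1e3, tol = 1e-8) {
  stats::setNames(as.numeric(solve(system$A, -system$b)),
                  system$metabolite_names)
}

#' @export
perturb_parameters.linear_system <- function(system, beta) {
  check_beta(beta)
  n <- length(system$sub)
  system$sub <- system$sub * (1 + stats::runif(n, -beta, beta))
  system$sup <- system$sup * (1 + stats::runif(n, -beta, beta))
  rebuild_matrix(system)
}

#' @export
apply_induced_variation.linear_system <- function(system, param_id, alpha) {
  check_alpha(alpha)
  loc <- parse_linear_param(param_id, length(system$b))
  if (loc$kind == "sub") {
    system$sub[loc$index] <- system$sub[loc$index] * (1 - alpha)
  } else if (loc$kind == "sup") {
    system$sup[loc$index] <- system$sup[loc$index] * (1 - alpha)
  } else {
    system$b[loc$index] <- system$b[loc$index] * (1 - alpha)
  }
  rebuild_matrix(system)
}

# "A(i,j)" with |i - j| == 1 addresses an exchange rate; "b(i)" an influx.
parse_linear_param <- function(param_id, J) {
  m <- regmatches(param_id,
                  regexec("^\\s*([Ab])\\((\\d+)(?:,(\\d+))?\\)\\s*$", param_id))[[1]]
  if (length(m) == 0)
    stop("unknown parameter '", param_id,
         "'; use \"A(i,j)\" with |i-j| = 1 or \"b(i)\"")
  if (m[2] == "b") {
    i <- as.integer(m[3])
    if (is.na(i) || i < 1 || i > J) stop("b index out of range in '", param_id, "'")
    return(list(kind = "b", index = i))
  }
  i <- as.integer(m[3]); j <- as.integer(m[4])
  if (is.na(j)) stop("matrix entry needs two indices in '", param_id, "'")
  if (i < 1 || j < 1 || i > J || j > J)
    stop("matrix index out of range in '", param_id, "'")
  if (i == j + 1L) return(list(kind = "sub", index = j))
  if (j == i + 1L) return(list(kind = "sup", index = i))
  stop("'", param_id, "' is not a perturbable off-diagonal entry ",
       "(diagonals are determined by the column-sum closure)")
}

#' Sampling grid of the linear-system experiments
#'
#' Twenty equispaced time points (6 + 5k) * 0.002 min for k = 0..19,
#' i.e. 0.012, 0.022, ..., 0.202 min.
#'
#' @return numeric vector of length 20.
#' @export
linear_time_grid <- function() {
  (6 + 5 * (0:19)) * 0.002
}

#' Sampling grid of the cholesterol-model experiments
#'
#' From the 1000-point source grid \code{10^seq(0, 6, length.out = 1000) - 1}
#' (days), takes the first point and then every 24th point until 21 points
#' are collected.
#'
#' @return numeric vector of length 21.
#' @export
cholesterol_time_grid <- function() {
  grid <- 10^seq(0, 6, length.out = 1000) - 1
  grid[seq(1L, by = 24L, length.out = 21L)]
}
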