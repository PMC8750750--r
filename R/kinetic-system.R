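#' Kinetic ODE system for cohort simulation
#'
#' A `kinetic_system` bundles the right-hand side of an ODE model of
#' metabolite dynamics, dx/dt = f(x; theta), with its named kinetic
#' parameters, initial concentrations and metabolite labels.  Any model in
#' this form (e.g. a glycolysis or whole-body cholesterol model with
#' user-supplied parameter values) can be plugged into the cohort generator;
#' the linear open system ships built in as the specialised
#' [linear_system()] class with a closed-form solver.
#'
#' @param rhs function of \code{(x, params)} returning dx/dt as a numeric
#'   vector of the same length as \code{x}.  Stoichiometry is folded into
#'   \code{rhs}.
#' @param params named numeric vector of kinetic parameters (defaults).
#' @param x0 numeric vector of initial concentrations.
#' @param metabolite_names optional character labels; defaults to
#'   \code{M1, M2, ...}.
#' @return an object of class \code{kinetic_system}.
#' @export
#' @examples
#' decay <- kinetic_system(
#'   rhs = function(x, p) c(-p["k1"] * x[1], p["k1"] * x[1] - p["k2"] * x[2]),
#'   params = c(k1 = 2, k2 = 1), x0 = c(1, 0))
#' simulate_system(decay, c(0.1, 0.5, 1))
kinetic_system <- function(rhs, params, x0, metabolite_names = NULL) {
  stopifnot(is.function(rhs), is.numeric(params), is.numeric(x0))
  if (is.null(names(params)) || anyNA(names(params)) || any(names(params) == ""))
    stop("`params` must be a fully named numeric vector")
  if (is.null(metabolite_names))
    metabolite_names <- paste0("M", seq_along(x0))
  stopifnot(length(metabolite_names) == length(x0))
  test <- rhs(x0, params)
  if (length(test) != length(x0))
    stop("rhs output length (", length(test),
         ") does not match length of x0 (", length(x0), ")")
  structure(list(rhs = rhs, params = params, x0 = x0,
                 metabolite_names = metabolite_names),
            class = "kinetic_system")
}

#' @export
print.kinetic_system <- function(x, ...) {
  cat("<kinetic_system> ", length(x$x0), " metabolites, ",
      length(x$params), " kinetic parameters\n", sep = "")
  invisible(x)
}

#' Simulate metabolite trajectories of a kinetic system
#'
#' Solves the initial-value problem from t = 0 and returns concentrations at
#' the requested times.  Linear systems use the matrix-exponential closed
#' form; general kinetic systems are integrated with a stiff-capable adaptive
#' solver (\code{deSolve::ode}, lsoda, rtol 1e-8 / atol 1e-10) -- rate
#' constants in these models can span several orders of magnitude.
#'
#' @param system a [kinetic_system()] or [linear_system()].
#' @param times strictly increasing numeric vector of sampling times.
#' @param rtol,atol integrator tolerances (kinetic systems only).
#' @return a J x K matrix (metabolites x time) with dimnames.
#' @export
simulate_system <- function(system, times, rtol = 1e-8, atol = 1e-10) {
  UseMethod("simulate_system")
}

#' @export
simulate_system.kinetic_system <- function(system, times, rtol = 1e-8,
                                           atol = 1e-10) {
  check_times(times)
  x0 <- system$x0
  # deSolve needs t = 0 in the grid to anchor the initial state
  grid <- times
  prepend <- grid[1] > 0
  if (prepend) grid <- c(0, grid)
  derivs <- function(t, y, parms) list(system$rhs(y, parms))
  sol <- deSolve::ode(y = x0, times = grid, func = derivs,
                      parms = system$params, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(sol, "istate")[1], ")")
  conc <- t(unclass(sol)[, -1, drop = FALSE])
  if (prepend) conc <- conc[, -1, drop = FALSE]
  if (anyNA(conc) || any(!is.finite(conc)))
    stop("ODE integration produced non-finite concentrations")
  dimnames(conc) <- list(system$metabolite_names, signif(times, 8))
  conc
}

#' Steady state of a kinetic system
#'
#' For linear systems the steady state solves A x + b = 0 exactly; for
#' general kinetic systems the ODE is integrated until the relative change
#' of the state over the last decade of a long horizon falls below `tol`.
#'
#' @param system a [kinetic_system()] or [linear_system()].
#' @param t_max integration horizon used for general systems.
#' @param tol relative-change threshold declaring convergence.
#' @return numeric vector of steady-state concentrations.
#' @export
steady_state <- function(system, t_max = 1e3, tol = 1e-8) {
  UseMethod("steady_state")
}

#' @export
steady_state.kinetic_system <- function(system, t_max = 1e3, tol = 1e-8) {
  traj <- simulate_system(system, c(0.9 * t_max, t_max))
  rel <- fnorm(traj[, 2] - traj[, 1]) / max(fnorm(traj[, 2]), .Machine$double.eps)
  if (rel > tol)
    warning("state still changing at t_max (relative change ", signif(rel, 3),
            "); steady state may be inaccurate")
  stats::setNames(traj[, 2], system$metabolite_names)
}

#' Randomly perturb kinetic parameters (individual variation)
#'
#' Each perturbable parameter p is replaced by p * (1 + u) with
#' u ~ Uniform(-beta, beta), drawn independently per parameter, so every
#' realized value stays within a hard relative bound beta of its default.
#' For the linear open system only the sub- and superdiagonal rates are
#' perturbed and the mass-conservation diagonal closure is recomputed
#' afterwards (see [linear_system()]).
#'
#' Draws come from the current RNG state; the cohort generator seeds a
#' dedicated stream per subject.
#'
#' @param system a [kinetic_system()] or [linear_system()].
#' @param beta non-negative relative perturbation level (e.g. 0.01 for
#'   "within 1 percent").
#' @return a system of the same class with perturbed parameters.
#' @export
perturb_parameters <- function(system, beta) {
  UseMethod("perturb_parameters")
}

#' @export
perturb_parameters.kinetic_system <- function(system, beta) {
  check_beta(beta)
  u <- stats::runif(length(system$params), -beta, beta)
  system$params <- system$params * (1 + u)
  system
}

#' Apply an induced variation (group-wise parameter knock-down)
#'
#' Multiplies one kinetic parameter by (1 - alpha), emulating e.g. a mutant
#' enzyme with fractionally reduced activity.  For the linear open system
#' the parameter is addressed as a matrix entry, e.g. \code{"A(7,6)"}, and
#' the column-sum closure is re-enforced afterwards.
#'
#' @param system a [kinetic_system()] or [linear_system()].
#' @param param_id name of the parameter (or \code{"A(i,j)"} for linear
#'   systems).
#' @param alpha fractional decrease in [0, 1).
#' @return the modified system.
#' @export
apply_induced_variation <- function(system, param_id, alpha) {
  UseMethod("apply_induced_variation")
}

#' @export
apply_induced_variation.kinetic_system <- function(system, param_id, alpha) {
  check_alpha(alpha)
  if (!param_id %in% names(system$params))
    stop("unknown parameter '", param_id, "'")
  system$params[param_id] <- system$params[param_id] * (1 - alpha)
  system
}

check_times <- function(times) {
  if (length(times) < 1L || any(diff(times) <= 0) || any(times < 0))
    stop("`times` must be non-negative and strictly increasing")
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0)
    stop("`beta` must be a single non-negative number")
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha >= 1)
    stop("`alpha` must be a single number in [0, 1)")
}

# ---- plug-in model registry -------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Register or retrieve plug-in kinetic models by name
#'
#' User-supplied kinetic models (a glycolysis model, a cholesterol model,
#' ...) can be registered under a name and then referenced from scenario
#' configurations.  The linear open system and its degenerate-case variant
#' are pre-registered as \code{"linear_open"} and \code{"linear_degenerate"}.
#'
#' @param name model name.
#' @param system a [kinetic_system()] or [linear_system()].
#' @return \code{register_kinetic_model} returns the system invisibly;
#'   \code{get_kinetic_model} returns the registered system;
#'   \code{list_kinetic_models} returns a character vector of names.
#' @export
register_kinetic_model <- function(name, system) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!inherits(system, c("kinetic_system", "linear_system")))
    stop("`system` must be a kinetic_system or linear_system")
  assign(name, system, envir = .model_registry)
  invisible(system)
}

#' @rdname register_kinetic_model
#' @export
get_kinetic_model <- function(name) {
  if (!exists(name, envir = .model_registry, inherits = FALSE))
    stop("no kinetic model registered under '", name, "'; available: ",
         paste(list_kinetic_models(), collapse = ", "))
  get(name, envir = .model_registry, inherits = FALSE)
}

#' @rdname register_kinetic_model
#' @export
list_kinetic_models <- function() {
  sort(ls(envir = .model_registry))
}

.onLoad <- function(libname, pkgname) {
  register_kinetic_model("linear_open", linear_system())
  register_kinetic_model("linear_degenerate", degenerate_linear_system())
}
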