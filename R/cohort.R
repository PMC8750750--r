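#' Specify individual and induced variation for a cohort group
#'
#' Individual variation is a per-subject random relative perturbation of the
#' kinetic parameters at level \code{beta} (each perturbable parameter is
#' multiplied by 1 + u, u ~ Uniform(-beta, beta)), emulating biological
#' variability.  Induced variation is a deterministic fractional knock-down
#' of specific parameters shared by every subject in the group (e.g. a
#' mutant enzyme at half activity: alpha = 0.5).
#'
#' @param beta non-negative individual-variation level.
#' @param induced list of induced variations, each a list/vector with
#'   elements \code{param} (parameter id) and \code{alpha} (fractional
#'   decrease in [0, 1)); empty for normal subjects.
#' @param mutant_init if TRUE, subjects in this group start from the
#'   steady state of the unperturbed base system instead of its x0 (used
#'   for mutant groups of plug-in whole-body models).
#' @return an object of class \code{variation_spec}.
#' @export
variation_spec <- function(beta = 0, induced = list(), mutant_init = FALSE) {
  check_beta(beta)
  induced <- lapply(induced, function(iv) {
    iv <- as.list(iv)
    if (is.null(iv$param) || is.null(iv$alpha))
      stop("each induced variation needs `param` and `alpha`")
    check_alpha(as.numeric(iv$alpha))
    list(param = as.character(iv$param), alpha = as.numeric(iv$alpha))
  })
  structure(list(beta = beta, induced = induced,
                 mutant_init = isTRUE(mutant_init)),
            class = "variation_spec")
}

#' Define a simulated cohort
#'
#' A cohort is an ordered set of groups, each with a label, a number of
#' subjects and a [variation_spec()], plus the common sampling time grid and
#' a root RNG seed.  Per-subject random draws use seeds derived from the
#' root seed and the (group, subject) indices, so the cohort is a pure
#' function of its configuration and adding a group never changes earlier
#' subjects.
#'
#' @param groups list of groups; each a list with \code{label},
#'   \code{n} (subjects, >= 1) and \code{variation} (a [variation_spec()]).
#' @param time_grid strictly increasing sampling times.
#' @param seed integer root seed.
#' @return an object of class \code{cohort_config}.
#' @export
#' @examples
#' cfg <- cohort_config(
#'   groups = list(
#'     list(label = "normal", n = 10, variation = variation_spec(beta = 0.01)),
#'     list(label = "abnormal_A(7,6)", n = 10,
#'          variation = variation_spec(beta = 0.01,
#'            induced = list(list(param = "A(7,6)", alpha = 0.5))))),
#'   time_grid = linear_time_grid(), seed = 1)
cohort_config <- function(groups, time_grid, seed = 1L) {
  check_times(time_grid)
  stopifnot(length(groups) >= 1L)
  groups <- lapply(groups, function(g) {
    g <- as.list(g)
    if (is.null(g$label) || is.null(g$n) || is.null(g$variation))
      stop("each group needs `label`, `n` and `variation`")
    if (!inherits(g$variation, "variation_spec"))
      stop("group `variation` must be a variation_spec")
    g$n <- as.integer(g$n)
    if (g$n < 1L) stop("each group needs n >= 1 subjects")
    g
  })
  structure(list(groups = groups, time_grid = as.numeric(time_grid),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Three-way metabolomics data container
#'
#' Holds an I x J x K array (subjects x metabolites x time) together with
#' the subject group labels, metabolite names, sampling times and an
#' optional binary observation mask W (1 = observed, 0 = missing).
#'
#' @param values numeric I x J x K array.
#' @param subject_groups length-I character vector of group labels.
#' @param metabolite_names length-J character vector.
#' @param times length-K numeric vector.
#' @param mask optional binary array with the same dimensions as
#'   \code{values}.
#' @return an object of class \code{metabolomics_tensor}.
#' @export
metabolomics_tensor <- function(values, subject_groups, metabolite_names,
                                times, mask = NULL) {
  stopifnot(length(dim(values)) == 3L)
  d <- dim(values)
  stopifnot(length(subject_groups) == d[1], length(metabolite_names) == d[2],
            length(times) == d[3])
  if (!is.null(mask)) {
    if (!identical(dim(mask), d)) stop("mask shape must equal values shape")
    if (!all(mask %in% c(0, 1))) stop("mask entries must be 0 or 1")
    if (any(!is.finite(values[mask == 1])))
      stop("values must be finite at observed entries")
  } else if (any(!is.finite(values))) {
    stop("values must be finite")
  }
  dimnames(values) <- list(make.unique(paste(subject_groups,
                                             seq_len(d[1]), sep = "_")),
                           metabolite_names, signif(times, 8))
  structure(list(values = values, subject_groups = as.character(subject_groups),
                 metabolite_names = as.character(metabolite_names),
                 times = as.numeric(times), mask = mask),
            class = "metabolomics_tensor")
}

#' @export
print.metabolomics_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<metabolomics_tensor> ", d[1], " subjects x ", d[2], " metabolites x ",
      d[3], " time points\n", sep = "")
  cat("  groups: ", paste(sprintf("%s (n=%d)", names(table(x$subject_groups)),
                                  table(x$subject_groups)), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$mask))
    cat("  mask: ", sum(x$mask == 0), " of ", length(x$mask),
        " entries missing\n", sep = "")
  invisible(x)
}

#' @export
dim.metabolomics_tensor <- function(x) dim(x$values)

#' Generate a simulated cohort tensor
#'
#' For every subject: seed a dedicated RNG stream, draw the individual
#' parameter perturbation at the group's beta, apply the group's induced
#' knock-downs, simulate the trajectory on the cohort time grid, and stack
#' the J x K trajectories into an I x J x K tensor.
#'
#' @param config a [cohort_config()].
#' @param system the base [kinetic_system()]/[linear_system()], or the name
#'   of a registered model (see [register_kinetic_model()]).
#' @return a [metabolomics_tensor()] (no mask).
#' @export
generate_cohort <- function(config, system = "linear_open") {
  stopifnot(inherits(config, "cohort_config"))
  if (is.character(system)) system <- get_kinetic_model(system)
  slabs <- list()
  groups_out <- character(0)
  for (g in seq_along(config$groups)) {
    grp <- config$groups[[g]]
    vs <- grp$variation
    base <- system
    if (vs$mutant_init) base$x0 <- unname(steady_state(system))
    for (s in seq_len(grp$n)) {
      set.seed(derive_seed(config$seed, g, s))
      subj <- perturb_parameters(base, vs$beta)
      for (iv in vs$induced)
        subj <- apply_induced_variation(subj, iv$param, iv$alpha)
      traj <- tryCatch(simulate_system(subj, config$time_grid),
                       error = function(e)
                         stop("simulation failed for subject ", s,
                              " of group '", grp$label, "': ",
                              conditionMessage(e)))
      slabs[[length(slabs) + 1L]] <- traj
      groups_out <- c(groups_out, grp$label)
    }
  }
  I <- length(slabs)
  J <- nrow(slabs[[1]]); K <- ncol(slabs[[1]])
  values <- array(0, dim = c(I, J, K))
  for (i in seq_len(I)) values[i, , ] <- slabs[[i]]
  metabolomics_tensor(values, groups_out,
                      metabolite_names = rownames(slabs[[1]]),
                      times = config$time_grid)
}

#' Add homoscedastic noise at a fixed relative Frobenius level
#'
#' Returns X + eta * N * ||X|| / ||N|| with N i.i.d. standard normal, so the
#' added term has Frobenius norm exactly eta * ||X||.  A zero tensor is
#' returned unchanged (the noise scale collapses).  Draws come from the
#' current RNG state.
#'
#' @param X numeric array or [metabolomics_tensor()].
#' @param eta non-negative relative noise level.
#' @return same type as \code{X}.
#' @export
add_noise <- function(X, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || is.na(eta) || eta < 0)
    stop("`eta` must be a single non-negative number")
  V <- tensor_values(X)
  nx <- fnorm(V)
  if (eta > 0 && nx > 0) {
    N <- array(stats::rnorm(length(V)), dim = dim(V))
    V <- V + eta * N * (nx / fnorm(N))
  }
  if (inherits(X, "metabolomics_tensor")) {
    X$values[] <- V
    X
  } else V
}

#' Draw a random missing-entry mask
#'
#' Sets exactly \code{round(fraction * prod(shape))} entries to 0 (missing),
#' chosen uniformly without replacement from all entries; the rest are 1.
#' Draws come from the current RNG state.
#'
#' @param shape integer vector of array dimensions.
#' @param fraction missing fraction in [0, 1).
#' @return a binary array of dimension \code{shape}.
#' @export
make_missing_mask <- function(shape, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction >= 1)
    stop("`fraction` must be in [0, 1)")
  n <- prod(shape)
  W <- array(1, dim = shape)
  n0 <- round(fraction * n)
  if (n0 > 0) W[sample.int(n, n0)] <- 0
  W
}

#' Long-format export of a metabolomics tensor
#'
#' @param X a [metabolomics_tensor()].
#' @return a data.frame with columns subject, group, metabolite, time,
#'   value and (if masked) observed.
#' @export
tensor_to_long <- function(X) {
  stopifnot(inherits(X, "metabolomics_tensor"))
  d <- dim(X$values)
  out <- data.frame(
    subject = rep(dimnames(X$values)[[1]], times = d[2] * d[3]),
    group = rep(X$subject_groups, times = d[2] * d[3]),
    metabolite = rep(rep(X$metabolite_names, each = d[1]), times = d[3]),
    time = rep(X$times, each = d[1] * d[2]),
    value = as.vector(X$values),
    stringsAsFactors = FALSE)
  if (!is.null(X$mask)) out$observed <- as.integer(as.vector(X$mask))
  out
}

#' Write a cohort tensor to plain-text files
#'
#' Writes a long-format CSV (\code{<stem>_long.csv}) and a sidecar CSV of
#' subject group labels (\code{<stem>_subjects.csv}).
#'
#' @param X a [metabolomics_tensor()].
#' @param stem output path stem.
#' @return invisibly, the paths written.
#' @export
write_tensor <- function(X, stem) {
  stopifnot(inherits(X, "metabolomics_tensor"))
  long_path <- paste0(stem, "_long.csv")
  subj_path <- paste0(stem, "_subjects.csv")
  utils::write.csv(tensor_to_long(X), long_path, row.names = FALSE)
  utils::write.csv(data.frame(subject = dimnames(X$values)[[1]],
                              group = X$subject_groups),
                   subj_path, row.names = FALSE)
  invisible(c(long_path, subj_path))
}

#' Read a cohort configuration from JSON or YAML
#'
#' The document mirrors [cohort_config()]: top-level \code{seed},
#' \code{time_grid} (or \code{time_grid_name}, one of
#' \code{"linear"}/\code{"cholesterol"}), and \code{groups}, each with
#' \code{label}, \code{n}, \code{beta}, optional \code{induced} (list of
#' \code{\{param, alpha\}}) and optional \code{mutant_init}.
#'
#' @param path path to a .json, .yml or .yaml file.
#' @return a [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the jsonlite package")
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else stop("unsupported config extension '.", ext, "'")
  tg <- if (!is.null(doc[["time_grid"]])) {
    as.numeric(unlist(doc[["time_grid"]]))
  } else {
    switch(doc[["time_grid_name"]] %||% "linear",
           linear = linear_time_grid(),
           cholesterol = cholesterol_time_grid(),
           stop("unknown time_grid_name '", doc[["time_grid_name"]], "'"))
  }
  groups <- lapply(doc$groups, function(g)
    list(label = g$label, n = g$n,
         variation = variation_spec(
           beta = as.numeric(g$beta %||% 0),
           induced = g$induced %||% list(),
           mutant_init = isTRUE(g$mutant_init))))
  cohort_config(groups, tg, seed = doc$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
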