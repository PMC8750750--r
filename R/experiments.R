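#' Subject-mode cosine similarity of the first two components
#'
#' C12 is the cosine similarity between the first two columns of a fitted
#' model's subject-mode factor.  |C12| near 1 signals rank deficiency in
#' the subjects mode (the two components share one subject profile), the
#' situation the Paralind model is designed for.  The signed value depends
#' on the package's component sign convention, so the absolute value is
#' reported alongside it.
#'
#' @param model a \code{cp_model} or \code{paralind_model} with R >= 2.
#' @return list with \code{c12} (signed) and \code{abs_c12}.
#' @export
subject_similarity <- function(model) {
  A <- effective_subject_factor(model)
  if (ncol(A) < 2) return(list(c12 = NA_real_, abs_c12 = NA_real_))
  c12 <- cosine_similarity(A[, 1], A[, 2])
  list(c12 = c12, abs_c12 = abs(c12))
}

#' CP model-selection table
#'
#' Fits a CP model for each candidate number of components and tabulates
#' the explained fit, core consistency, scalar Tucker congruence and the
#' subject-mode similarity of the first two components -- the quantities
#' used to choose the number of components and detect rank deficiency or
#' degeneracy.
#'
#' @param X preprocessed data array or [metabolomics_tensor()].
#' @param R_values integer vector of candidate component numbers.
#' @param n_starts random starts per fit.
#' @param seed fitting seed.
#' @param ... further arguments passed to [fit_options()].
#' @return a data.frame with columns R, fit, cc, tc, c12, abs_c12, plus an
#'   attribute \code{"models"} holding the fitted models.
#' @export
run_model_selection <- function(X, R_values = 1:3, n_starts = 20L, seed = 1L,
                                ...) {
  models <- list()
  rows <- lapply(R_values, function(R) {
    m <- fit_cp(X, fit_options(n_components = R, n_starts = n_starts,
                               seed = seed, ...))
    models[[as.character(R)]] <<- m
    tc <- tucker_congruence(m)
    sim <- subject_similarity(m)
    data.frame(R = R, fit = m$fit, cc = core_consistency(X, m),
               tc = tc$tc, c12 = sim$c12, abs_c12 = sim$abs_c12)
  })
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}

# Built-in scenario definitions: the 10 + 10 subject linear-system cohorts
# with a 50% knock-down of A(7,6) in the abnormal group.
scenario_catalog <- function() {
  one_source <- function(beta) list(
    system = "linear_open",
    groups = list(
      list(label = "normal", n = 10L,
           variation = variation_spec(beta = beta)),
      list(label = "abnormal_A(7,6)", n = 10L,
           variation = variation_spec(
             beta = beta,
             induced = list(list(param = "A(7,6)", alpha = 0.5))))),
    time_grid = linear_time_grid())
  list(
    linear_one_source_b001 = c(one_source(0.01),
                               list(chosen = paralind_spec(1L, 2L, c(1L, 1L)))),
    linear_one_source_b030 = c(one_source(0.30),
                               list(chosen = cp_spec(2L))),
    linear_degenerate_case = {
      sc <- one_source(0.01)
      sc$system <- "linear_degenerate"
      c(sc, list(chosen = paralind_spec(1L, 2L, c(1L, 1L))))
    })
}

#' Run a built-in experiment scenario end to end
#'
#' Generates the scenario's cohort, preprocesses it, runs CP model selection
#' over \code{R_values}, fits the scenario's chosen model (Paralind(1,2,2)
#' at low individual variation, where the subject mode is rank deficient;
#' the 2-component CP model at high individual variation), and optionally
#' runs the missing-data cross-validation comparison between the two.
#' All artifacts are written under \code{out_dir} when given, together with
#' a run manifest (scenario, seed, package version).
#'
#' @param name one of \code{"linear_one_source_b001"} (individual variation
#'   beta = 0.01), \code{"linear_one_source_b030"} (beta = 0.3), or
#'   \code{"linear_degenerate_case"} (the parameter setting that makes the
#'   CP model degenerate).
#' @param seed root seed for cohort generation and fitting.
#' @param out_dir optional output directory.
#' @param R_values candidate component numbers for model selection.
#' @param n_starts random starts per single-model fit.
#' @param crossval run the cross-validation comparison (CP(R=2) vs
#'   Paralind(1,2,2); adds substantial runtime).
#' @param crossval_reps,crossval_starts replicates and per-fit starts for
#'   the cross-validation stage.
#' @return list with \code{tensor}, \code{preprocessed}, \code{selection}
#'   (model-selection table), \code{chosen} (fitted chosen model),
#'   \code{crossval} (a \code{crossval_report} or NULL), \code{manifest}.
#' @export
run_scenario <- function(name, seed = 1L, out_dir = NULL, R_values = 1:3,
                         n_starts = 20L, crossval = FALSE,
                         crossval_reps = 20L, crossval_starts = 2L) {
  catalog <- scenario_catalog()
  if (!name %in% names(catalog))
    stop("unknown scenario '", name, "'; choose one of: ",
         paste(names(catalog), collapse = ", "))
  sc <- catalog[[name]]
  cfg <- cohort_config(sc$groups, sc$time_grid, seed = seed)
  tensor <- generate_cohort(cfg, sc$system)
  pp <- preprocess_tensor(tensor)
  selection <- run_model_selection(pp$values, R_values = R_values,
                                   n_starts = n_starts, seed = seed)
  chosen <- fit_model(pp$values, sc$chosen, seed = derive_seed(seed, 17L, 1L))
  cv <- NULL
  if (crossval) {
    specs <- list(cp_spec(2L, n_starts = crossval_starts, tol = 1e-8,
                          max_iters = 2000L),
                  paralind_spec(1L, 2L, c(1L, 1L), n_starts = crossval_starts,
                                tol = 1e-8, max_iters = 2000L))
    cv <- crossval_compare(tensor, specs, eta = 0.3, missing_fraction = 0.2,
                           n_reps = crossval_reps,
                           seed = derive_seed(seed, 29L, 1L))
  }
  manifest <- data.frame(
    scenario = name, seed = seed,
    system = sc$system,
    n_subjects = dim(tensor)[1], n_metabolites = dim(tensor)[2],
    n_times = dim(tensor)[3],
    n_starts = n_starts,
    chosen_model = sc$chosen$label,
    package_version = as.character(utils::packageVersion("metabotensor")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tensor(tensor, file.path(out_dir, "cohort"))
    write_preprocess_state(pp$state, file.path(out_dir, "preprocess"))
    utils::write.csv(selection, file.path(out_dir, "model_selection.csv"),
                     row.names = FALSE)
    write_factors(chosen, file.path(out_dir, "chosen"),
                  mode_labels = list(subjects = dimnames(tensor$values)[[1]],
                                     metabolites = tensor$metabolite_names,
                                     time = signif(tensor$times, 8)))
    if (!is.null(cv)) write_crossval_report(cv, file.path(out_dir, "crossval"))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(tensor = tensor, preprocessed = pp, selection = selection,
       chosen = chosen, crossval = cv, manifest = manifest)
}

#' Convenience constructor for the one-source linear-system cohort
#'
#' The 20-subject design used throughout the linear-system experiments:
#' 10 normal subjects with individual variation at level beta, and 10
#' abnormal subjects that additionally carry a 50% knock-down of the
#' exchange rate A(7,6).
#'
#' @param beta individual-variation level.
#' @param seed root seed.
#' @param alpha induced fractional decrease of A(7,6).
#' @param n_per_group subjects per group.
#' @return a [cohort_config()].
#' @export
linear_one_source_config <- function(beta = 0.01, seed = 1L, alpha = 0.5,
                                     n_per_group = 10L) {
  cohort_config(
    groups = list(
      list(label = "normal", n = n_per_group,
           variation = variation_spec(beta = beta)),
      list(label = "abnormal_A(7,6)", n = n_per_group,
           variation = variation_spec(
             beta = beta,
             induced = list(list(param = "A(7,6)", alpha = alpha))))),
    time_grid = linear_time_grid(), seed = seed)
}
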