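#!/usr/bin/env Rscript
# Generates the linear-open-system cohorts used throughout the analysis and
# writes them (long format) plus a preview of the preprocessing state.
#
# Three 20-subject cohorts (10 normal + 10 abnormal_A(7,6) with a 50%
# knock-down of the M6 -> M7 exchange rate), sampled at the 20-point grid
# 0.012..0.202 min:
#   - beta = 0.01 (small individual variation; the rank-deficient regime)
#   - beta = 0.30 (large individual variation)
#   - beta = 0.01 on the degenerate-case parameter variant

library(metabotensor)

out <- file.path("results", "cohorts")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

runs <- list(
  b001 = list(beta = 0.01, system = "linear_open"),
  b030 = list(beta = 0.30, system = "linear_open"),
  degenerate_b001 = list(beta = 0.01, system = "linear_degenerate"))

for (name in names(runs)) {
  r <- runs[[name]]
  cfg <- linear_one_source_config(beta = r$beta, seed = seed)
  X <- generate_cohort(cfg, r$system)
  pp <- preprocess_tensor(X)
  write_tensor(X, file.path(out, name))
  write_preprocess_state(pp$state, file.path(out, paste0(name, "_pp")))
  cat(sprintf("%-16s %s tensor, %d x %d x %d; slice RMS range %.3g..%.3g\n",
              name, r$system, dim(X)[1], dim(X)[2], dim(X)[3],
              min(pp$state$scales), max(pp$state$scales)))
}

cat("\nCohorts written under", out, "\n")
cat("Metabolite concentration ranges differ by orders of magnitude across\n")
cat("the chain, which is why the metabolites mode is RMS-scaled before\n")
cat("any tensor model is fitted.\n")
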