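#!/usr/bin/env Rscript
# Fits the Paralind(1,2,2) model (shared subject profile, orthogonal
# metabolites factors, non-negative time factors) to the beta = 0.01 cohort
# and contrasts it with the unrestricted 2-component CP model, and with the
# beta = 0.30 cohort where the rank deficiency disappears and CP is the
# model of choice.

library(metabotensor)

dir.create("results", showWarnings = FALSE)
seed <- 1L

# --- beta = 0.01: restricted model on rank-deficient data -------------------
cfg <- linear_one_source_config(beta = 0.01, seed = seed)
X <- generate_cohort(cfg)
pp <- preprocess_tensor(X)
cp2 <- fit_cp(pp$values, fit_options(2, n_starts = 20, seed = seed))
pl <- fit_paralind(pp$values, S = 1, R = 2, groups = c(1, 1),
                   opts = fit_options(2, n_starts = 20, seed = seed))

cat(sprintf("beta = 0.01:  CP(R=2) fit %.2f%%   Paralind(1,2,2) fit %.2f%%\n",
            cp2$fit, pl$fit))
cat("The Paralind fit is slightly lower, as it must be: the shared subject\n")
cat("profile is an extra restriction on the CP model.\n\n")

a <- (pl$A %*% pl$H)[, 1]
cat("Paralind subject profile by group (mean +/- sd):\n")
for (g in unique(X$subject_groups))
  cat(sprintf("  %-16s %+.3f +/- %.3f\n", g,
              mean(a[X$subject_groups == g]), sd(a[X$subject_groups == g])))
cat("Opposite signs: the single subject vector separates normal from\n")
cat("knock-down subjects. The metabolites factors localize the effect:\n")
B <- pl$B
for (r in 1:2) {
  top <- order(abs(B[, r]), decreasing = TRUE)[1:3]
  cat(sprintf("  comp %d largest |loadings|: %s; jump |b(M7) - b(M6)| = %.2f\n",
              r, paste0("M", top, collapse = ", "),
              abs(B[7, r] - B[6, r])))
}
cat("The jump between M6 and M7 sits exactly at the knocked-down exchange\n")
cat("rate A(7,6): the model places the group difference at the lesion.\n")

write_factors(pl, file.path("results", "paralind_b001"),
              mode_labels = list(subjects = dimnames(X$values)[[1]],
                                 metabolites = X$metabolite_names,
                                 time = signif(X$times, 8)))

# --- beta = 0.30: large individual variation, CP preferred ------------------
cfg30 <- linear_one_source_config(beta = 0.30, seed = seed)
pp30 <- preprocess_tensor(generate_cohort(cfg30))
cp30 <- fit_cp(pp30$values, fit_options(2, n_starts = 20, seed = seed))
sim30 <- subject_similarity(cp30)
cat(sprintf("\nbeta = 0.30:  CP(R=2) fit %.2f%%, C12 = %+.2f (|C12| = %.2f)\n",
            cp30$fit, sim30$c12, sim30$abs_c12))
cat("With 30x larger individual variation the rank deficiency is gone\n")
cat("(|C12| far from 1) and the unrestricted CP model is retained.\n")

write_factors(cp30, file.path("results", "cp_b030"))
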