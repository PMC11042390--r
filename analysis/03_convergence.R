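#!/usr/bin/env Rscript
# Convergence inference: do TMS- and lesion-derived circuits agree more than
# chance? Outcome-shuffle permutation test on the spatial correlation of the
# two combined maps, plus the mean cross-correlation over all dataset pairs.

source("analysis/00_common.R")

study <- build_study()
n_perm <- 1000L

pt <- permutation_similarity_test(
  study$datasets,
  split = list(a = c("tms_a", "tms_b"), b = c("lesion_a", "lesion_b")),
  n_permutations = n_perm, rng_seed = analysis_seed + 1L)
cat("TMS vs lesion combined maps: spatial r =", round(pt$observed, 3),
    ", permutation p =", signif(pt$p_value, 3), "\n")
write_permutation_json(pt, file.path(results_dir, "convergence_tms_lesion.json"))

mt <- mean_cross_correlation_test(study$datasets, n_permutations = n_perm,
                                  rng_seed = analysis_seed + 2L)
cat("Mean cross-correlation over all", length(study$datasets),
    "dataset pairs:", round(mt$observed, 3),
    ", permutation p =", signif(mt$p_value, 3), "\n")
write_permutation_json(mt, file.path(results_dir, "convergence_all_pairs.json"))
cat("Both tests shuffle each patient's (outcome, covariate) tuple within",
    "dataset and rebuild every map, so the null respects the imaging.\n")
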