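# Shared setup for the analysis drivers: one synthetic study specification,
# regenerated deterministically by every script from the same seed.
# Override the seed with:  Rscript analysis/0X_*.R <seed>

library(circuitmap)

analysis_seed <- local({
  a <- commandArgs(trailingOnly = TRUE)
  if (length(a) >= 1) as.integer(a[[1]]) else 1L
})

results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

study_spec <- function(seed = analysis_seed) synthetic_spec(rng_seed = seed)

# the full study: 2 scalp-TMS + 2 lesion training cohorts (n = 100 each)
# and a held-out bilateral-DBS cohort (n = 74)
build_study <- function(seed = analysis_seed) simulate_study(study_spec(seed))
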