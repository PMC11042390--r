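#!/usr/bin/env Rscript
# External validation on the held-out DBS cohort: the circuit is built
# entirely from TMS and lesion data, then each bilateral DBS field pair is
# scored by overlap (mean circuit value under the left field + under the
# right) and the scores are tested against anxiety change, controlling for
# depression change and baselines.

source("analysis/00_common.R")

study <- build_study()
combined <- weighted_mean_map(lapply(study$datasets, circuit_map))

scores <- vapply(score_cohort(study$dbs, combined), `[[`, numeric(1), "score")
pr <- predict_outcome_change(scores, study$dbs)
cat(sprintf("DBS overlap predicted anxiety change: partial r = %.3f, p = %.4g, n = %d\n",
            pr$r, pr$p, pr$n))

# permutation null bound: shuffle (outcome, covariate) tuples, keep scores
null_r <- vapply(1:100, function(i) {
  set.seed(analysis_seed * 1000L + i)
  idx <- sample.int(study$dbs$n)
  recs <- lapply(seq_len(study$dbs$n), function(j) {
    src <- study$dbs$records[[idx[j]]]
    patient_record(src$id, study$dbs$records[[j]]$site, src$anxiety,
                   src$depression, extra_covariates = src$extra_covariates)
  })
  predict_outcome_change(scores, cohort_dataset("null", "dbs", recs))$r
}, numeric(1))
cat(sprintf("95%% null bound from 100 shuffles: %.3f (observed %.3f)\n",
            quantile(null_r, 0.95), pr$r))

out <- data.frame(id = vapply(study$dbs$records, `[[`, "", "id"),
                  overlap_score = scores,
                  anxiety_change = vapply(study$dbs$records, `[[`,
                                          numeric(1), "anxiety"))
write.csv(out, file.path(results_dir, "dbs_overlap_scores.csv"),
          row.names = FALSE)
jsonlite::write_json(list(r = pr$r, p = pr$p, n = pr$n,
                          null_bound_95 = unname(quantile(null_r, 0.95)),
                          rng_seed = analysis_seed),
                     file.path(results_dir, "dbs_prediction.json"),
                     auto_unbox = TRUE, digits = NA)
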