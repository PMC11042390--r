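test_that("connectivity scores: proportionality, anticorrelation, Pearson oracle", {
  g <- mm_grid(c(16, 16, 16))
  mask <- array(TRUE, c(16, 16, 16))
  set.seed(1)
  circ_vals <- rnorm(16^3)
  circ <- circuitmap:::new_circuit_map(volume_from_mask(g, mask, circ_vals),
                                       weight = 10, provenance = "toy")
  mk_conn <- function(vals) structure(
    list(zmap = volume_from_mask(g, mask, vals), site = NULL,
         n_subjects_used = 1L), class = "connectivity_map")
  expect_equal(site_connectivity_score(mk_conn(3.2 * circ_vals), circ)$score, 1)
  expect_equal(site_connectivity_score(mk_conn(-0.5 * circ_vals), circ)$score, -1)
  other <- rnorm(16^3)
  expect_equal(site_connectivity_score(mk_conn(other), circ)$score,
               cor(other, circ_vals), tolerance = 1e-12)
  sc <- site_connectivity_score(mk_conn(other), circ, patient_id = "p1")
  expect_equal(sc$method, "spatial_corr")
  expect_equal(sc$circuit_provenance, "toy")
})

test_that("DBS overlap: stated arithmetic, hemifield symmetry, empty-field zero", {
  g <- mm_grid(c(6, 6, 6))
  mask <- array(TRUE, c(6, 6, 6))
  vals <- numeric(216); vals[1] <- 0.2; vals[2] <- 0.4; vals[10] <- 0.1
  circ <- circuitmap:::new_circuit_map(volume_from_mask(g, mask, vals),
                                       weight = 1, provenance = "toy")
  l <- array(0, c(6, 6, 6)); l[1] <- 1; l[2] <- 1
  r <- array(0, c(6, 6, 6)); r[10] <- 1
  lv <- brain_volume(g, l); rv <- brain_volume(g, r)
  site <- dbs_pair_site(lv, rv)
  # mean{0.2, 0.4} + mean{0.1} = 0.3 + 0.1
  expect_equal(dbs_overlap_score(site, circ)$score, 0.4)
  # swapping hemifield labels leaves the sum unchanged
  expect_equal(dbs_overlap_score(dbs_pair_site(rv, lv), circ)$score, 0.4)
  # empty hemifield contributes exactly 0
  empty <- brain_volume(g, array(0, c(6, 6, 6)))
  expect_equal(dbs_overlap_score(dbs_pair_site(empty, rv), circ)$score, 0.1)
  # circuit uniformly zero under both fields
  expect_equal(dbs_overlap_score(site, circuitmap:::new_circuit_map(
    volume_from_mask(g, mask, numeric(216)), 1, "z"))$score, 0)
  # both hemifields outside the analysis mask
  m2 <- array(FALSE, c(6, 6, 6)); m2[100:216] <- TRUE
  circ2 <- circuitmap:::new_circuit_map(
    volume_from_mask(g, m2, rnorm(sum(m2))), 1, "m")
  expect_error(dbs_overlap_score(dbs_pair_site(lv, brain_volume(g, l)), circ2),
               "outside")
  expect_error(dbs_overlap_score(single_voxel_site(g, mask, 1L), circ), "DBS")
})

test_that("outcome prediction recovers the constructed effect size", {
  # y = beta * s + e  =>  cor(s, y) = beta / sqrt(beta^2 + sigma^2)
  set.seed(2)
  n <- 200; beta <- 0.8; sigma <- 1
  s <- rnorm(n)
  y <- beta * s + sigma * rnorm(n)
  r_theory <- beta / sqrt(beta^2 + sigma^2)
  g <- centered_grid(c(4, 4, 4), voxel = 2)
  mask <- array(TRUE, c(4, 4, 4))
  ds <- toy_cohort(matrix(rnorm(n * 64), n, 64), y, rnorm(n), g, mask)
  pr <- predict_outcome_change(s, ds, covariate_fields = character(0))
  expect_lt(abs(pr$r - r_theory), 0.1)
  expect_lt(pr$p, 1e-10)
  expect_equal(pr$n, n)
  expect_error(predict_outcome_change(rep(1, n), ds,
                                      covariate_fields = character(0)),
               "residual variance")
  expect_error(predict_outcome_change(s[1:10], ds), "align")
})

test_that("null scores reject at the nominal 5% rate", {
  g <- centered_grid(c(4, 4, 4), voxel = 2)
  mask <- array(TRUE, c(4, 4, 4))
  n <- 40
  hits <- vapply(1:100, function(i) {
    set.seed(300 + i)
    ds <- toy_cohort(matrix(rnorm(n * 64), n, 64), rnorm(n), rnorm(n), g, mask)
    pr <- predict_outcome_change(rnorm(n), ds, covariate_fields = "depression")
    pr$p < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 100)
  expect_lt(abs(mean(hits) - 0.05), 3 * se + 1e-9)
})

test_that("roi benchmark: circuit-as-ROI consistency and row counting", {
  g <- centered_grid(c(5, 5, 5), voxel = 2)
  mask <- array(TRUE, c(5, 5, 5))
  n <- 30; V <- 125
  set.seed(4)
  mkds <- function(nm) toy_cohort(matrix(rnorm(n * V), n, V),
                                  rnorm(n), rnorm(n), g, mask, name = nm)
  train <- list(a = mkds("a"), b = mkds("b"), c = mkds("c"))
  evald <- mkds("eval")
  circ <- weighted_mean_map(lapply(train, circuit_map,
                                   covariate_fields = "depression"))
  # the combined circuit passed as a continuous "ROI" must reproduce the
  # circuit row exactly (the eval dataset is not in the training set)
  rois <- list(self = circ$rmap,
               box = brain_volume(g, array(as.numeric(seq_len(V) < 30),
                                           c(5, 5, 5))))
  tab <- roi_benchmark(rois, list(evald), train,
                       covariate_fields = "depression",
                       outcome_field = "anxiety")
  expect_equal(nrow(tab), 3L)  # circuit + 2 ROIs, 1 dataset
  r_circ <- tab$r[tab$roi == "circuit"]
  r_self <- tab$r[tab$roi == "self"]
  expect_equal(r_circ, r_self, tolerance = 1e-10)
  sc <- score_cohort(evald, circ)
  pr <- predict_outcome_change(sc, evald, covariate_fields = "depression")
  expect_equal(r_circ, pr$r, tolerance = 1e-10)
  expect_error(roi_benchmark(list(empty = brain_volume(
    g, array(0, c(5, 5, 5)), mask)), list(evald), train), "empty|positive|analysable")
})

test_that("specificity profile ranks the driving measure first", {
  set.seed(5)
  n <- 120
  trait <- rnorm(n)
  state <- 0.5 * trait + sqrt(0.75) * rnorm(n)
  mdd <- as.numeric(runif(n) < 0.3)
  ptsd <- as.numeric(runif(n) < 0.2)
  measure <- 0.9 * trait + 0.3 * rnorm(n)   # driven by trait only
  g <- centered_grid(c(4, 4, 4), voxel = 2)
  mask <- array(TRUE, c(4, 4, 4))
  ds <- toy_cohort(matrix(rnorm(n * 64), n, 64), rnorm(n), rnorm(n), g, mask,
                   extras = list(trait = trait, state = state,
                                 mdd = mdd, ptsd = ptsd))
  prof <- specificity_profile(measure, ds, primary = "trait",
                              controls = c("state", "mdd", "ptsd"))
  expect_equal(prof$rank_of_primary, 1L)
  r_trait <- prof$measures$r[prof$measures$measure == "trait"]
  r_state <- prof$measures$r[prof$measures$measure == "state"]
  expect_gt(abs(r_trait), abs(r_state) + 0.2)
  expect_error(specificity_profile(measure, ds, primary = "absent",
                                   controls = "state"), "missing")
  expect_error(specificity_profile(measure, ds, primary = "trait",
                                   controls = c("state", "state2")), "missing")
})

test_that("null specificity ranks are roughly uniform across replicates", {
  g <- centered_grid(c(4, 4, 4), voxel = 2)
  mask <- array(TRUE, c(4, 4, 4))
  n <- 60
  ranks <- vapply(1:60, function(i) {
    set.seed(600 + i)
    ds <- toy_cohort(matrix(rnorm(n * 64), n, 64), rnorm(n), rnorm(n), g, mask,
                     extras = list(m1 = rnorm(n), m2 = rnorm(n),
                                   m3 = rnorm(n), m4 = rnorm(n)))
    specificity_profile(rnorm(n), ds, primary = "m1",
                        controls = c("m2", "m3", "m4"))$rank_of_primary
  }, integer(1))
  tab <- tabulate(ranks, 4)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("subgroup prediction pools by group size and reduces for one dataset", {
  g <- centered_grid(c(5, 5, 5), voxel = 2)
  mask <- array(TRUE, c(5, 5, 5))
  n <- 60; V <- 125
  set.seed(7)
  mkds <- function(nm, seed) {
    set.seed(seed)
    Z <- matrix(rnorm(n * V), n, V)
    grp <- rep(c(0, 1), each = n / 2)
    y <- Z[, 5] + rnorm(n)          # same effect in both groups
    toy_cohort(Z, y, rnorm(n), g, mask, name = nm,
               extras = list(anx_disorder = grp))
  }
  ds <- list(a = mkds("a", 71), b = mkds("b", 72))
  out <- subgroup_prediction(ds, "anx_disorder",
                             covariate_fields = "depression")
  expect_equal(sort(out$group), c(0, 1))
  expect_lt(abs(out$pooled_r[1] - out$pooled_r[2]), 0.35)
  expect_true(all(out$pooled_r > 0))
  # single dataset: pooled r equals that dataset's per-group r
  one <- subgroup_prediction(ds["a"], "anx_disorder",
                             covariate_fields = "depression")
  circ_a <- circuit_map(ds$a, covariate_fields = "depression")
  recs0 <- ds$a$records[vapply(ds$a$records, function(r)
    r$extra_covariates$anx_disorder, numeric(1)) == 0]
  sub0 <- cohort_dataset("a0", "lesion", recs0)
  pr0 <- predict_outcome_change(score_cohort(sub0, circ_a), sub0,
                                covariate_fields = "depression")
  expect_equal(one$pooled_r[one$group == 0], pr0$r, tolerance = 1e-10)
})
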