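# generator tests run at reduced desk-scale sizes (few subjects, short
# series) except where a stated condition fixes them

small_spec <- function(...) {
  args <- list(n_subjects = 6, n_timepoints = 60, n_patients = 30)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_spec, args)
}

test_that("generation is bitwise deterministic given the seed", {
  sp <- small_spec(rng_seed = 42)
  c1 <- make_connectome(sp); c2 <- make_connectome(sp)
  expect_identical(c1$subjects, c2$subjects)
  circ <- make_circuit(sp)
  co1 <- make_cohort(sp, circ, c1, name = "d")
  co2 <- make_cohort(sp, circ, c2, name = "d")
  expect_identical(cohort_table(co1), cohort_table(co2))
  # and a different seed moves the data
  expect_false(identical(make_connectome(small_spec(rng_seed = 43))$subjects,
                         c1$subjects))
})

test_that("zero smoothness and zero latent strength give white noise", {
  sp <- small_spec(smoothness_mm = 0, latent_strength = 0, rng_seed = 5,
                   n_subjects = 1, n_timepoints = 120)
  con <- make_connectome(sp)
  ts <- con$subjects[[1]]
  # neighbouring in-mask voxels: |r| below 3/sqrt(T)
  i <- which(con$mask_idx == con$mask_idx[1] + 1L)  # adjacent pair if present
  pairs <- cbind(seq_len(50), seq_len(50) + 1L)
  rs <- vapply(seq_len(nrow(pairs)), function(k)
    cor(ts[, pairs[k, 1]], ts[, pairs[k, 2]]), numeric(1))
  expect_lt(mean(abs(rs)), 3 / sqrt(sp$n_timepoints))
  # unit variance per voxel (normalized noise)
  expect_lt(abs(mean(apply(ts[, 1:40], 2, var)) - 1), 0.35)
})

test_that("smoothing induces neighbour correlation", {
  sp <- small_spec(smoothness_mm = 4, latent_strength = 0, rng_seed = 6,
                   n_subjects = 1, n_timepoints = 120)
  ts <- make_connectome(sp)$subjects[[1]]
  rs <- vapply(1:50, function(k) cor(ts[, k], ts[, k + 1]), numeric(1))
  expect_gt(mean(rs), 0.5)
})

test_that("seed maps from a positive-pole site resemble the planted circuit", {
  sp <- small_spec(rng_seed = 7)
  circ <- make_circuit(sp)
  con <- make_connectome(sp, circ)
  # site at the positive peak
  peak_mm <- sp$circuit_peaks[[1]]$center_mm
  site <- tms_site(con$grid, peak_mm)
  cm <- seed_connectivity(site, con)
  expect_gt(spatial_correlation(cm$zmap, circ), 0.3)
})

test_that("planted circuit geometry: peak placement, symmetry, cluster recovery", {
  # a single positive peak centred exactly on a voxel: maximum at that voxel
  sp1 <- synthetic_spec(circuit_peaks = list(
    list(center_mm = c(7, 7, 7), sign = 1, width_mm = 5)))
  circ1 <- make_circuit(sp1)
  vox <- nearest_voxel(circ1$grid, c(7, 7, 7))
  lin <- 1L + vox[1] + 16L * (vox[2] + 16L * vox[3])
  expect_equal(which.max(replace(circ1$data, is.na(circ1$data), -Inf)), lin)
  expect_equal(max(circ1$data, na.rm = TRUE), 1)
  sp <- small_spec(rng_seed = 1)
  circ <- make_circuit(sp)
  pk1 <- sp$circuit_peaks[[1]]
  # two opposite equal peaks on a symmetric mask sum to ~0
  expect_lt(abs(sum(circ$data[circ$brain_mask])), 1e-6)
  # cluster peaks recover both pole centres within one voxel (2 mm)
  pos <- cluster_peaks(circ, threshold = 0.5, k = 2)
  negv <- brain_volume(circ$grid, -circ$data, circ$brain_mask)
  neg <- cluster_peaks(negv, threshold = 0.5, k = 2)
  expect_lt(max(abs(unlist(pos[1, 1:3]) - pk1$center_mm)), 2.01)
  expect_lt(max(abs(unlist(neg[1, 1:3]) - sp$circuit_peaks[[2]]$center_mm)), 2.01)
  expect_error(make_circuit(synthetic_spec(circuit_peaks = list(
    list(center_mm = c(99, 0, 0), sign = 1, width_mm = 5)))), "outside")
})

test_that("anxiety-depression confound lands at the target correlation", {
  sp <- synthetic_spec(n_subjects = 4, n_timepoints = 40, n_patients = 300,
                       rng_seed = 11, modality = "dbs")
  co <- make_cohort(sp, compute_conn = FALSE)
  tab <- cohort_table(co)
  expect_lt(abs(cor(tab$anxiety, tab$depression) - 0.53), 0.1)
  # and the knob moves: rho = 0 gives near-zero correlation
  sp0 <- synthetic_spec(n_subjects = 4, n_timepoints = 40, n_patients = 300,
                        rng_seed = 11, modality = "dbs", confound_rho = 0)
  tab0 <- cohort_table(make_cohort(sp0, compute_conn = FALSE))
  expect_lt(abs(cor(tab0$anxiety, tab0$depression)), 0.15)
})

test_that("cohorts carry modality-appropriate sites and covariates", {
  sp <- small_spec(rng_seed = 20, n_patients = 12)
  circ <- make_circuit(sp)
  con <- make_connectome(sp, circ)
  les <- make_cohort(sp, circ, con, name = "l", modality = "lesion")
  expect_true(all(vapply(les$records, function(r) r$site$kind == "lesion",
                         logical(1))))
  sizes <- vapply(les$records, function(r) r$site$size_voxels, integer(1))
  expect_true(all(sizes >= 3 & sizes <= 10))
  expect_true(all(vapply(les$records, function(r)
    r$extra_covariates$lesion_size == r$site$size_voxels, logical(1))))
  tms <- make_cohort(sp, circ, con, name = "t", modality = "tms_scalp")
  expect_true(all(vapply(tms$records, function(r)
    !is.null(r$extra_covariates$baseline), logical(1))))
  dbs <- make_cohort(sp, circ, NULL, name = "d", modality = "dbs",
                     compute_conn = FALSE)
  expect_true(all(vapply(dbs$records, function(r) r$site$kind == "dbs_pair",
                         logical(1))))
  # DBS hemifields are mirrored in x
  r1 <- dbs$records[[1]]$site
  il <- which(r1$weights$data > 0); ir <- which(r1$weights_right$data > 0)
  xl <- voxel_world_coords(r1$weights$grid, il)
  xr <- voxel_world_coords(r1$weights$grid, ir)
  expect_equal(sort(-xl[, 1]), sort(xr[, 1]), tolerance = 1e-9)
})

test_that("true scores are predictive at beta > 0 and calibrated at beta = 0", {
  # with the effect on, true scores correlate with outcome
  sp <- synthetic_spec(n_patients = 150, effect_beta = 0.8, rng_seed = 30,
                       modality = "dbs")
  tab <- cohort_table(make_cohort(sp, compute_conn = FALSE))
  expect_gt(cor(tab$true_score, tab$anxiety), 0.3)
  # with beta = 0, prediction from true scores rejects at the nominal rate
  hits <- vapply(1:100, function(i) {
    spn <- synthetic_spec(n_patients = 40, effect_beta = 0, rng_seed = 900 + i,
                          modality = "dbs", n_subjects = 1, n_timepoints = 32)
    co <- make_cohort(spn, compute_conn = FALSE)
    t2 <- cohort_table(co)
    pr <- predict_outcome_change(t2$true_score, co,
                                 covariate_fields = "depression")
    pr$p < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 100)
  expect_lt(abs(mean(hits) - 0.05), 3 * se + 1e-9)
})

test_that("a written study round-trips through its manifest and files", {
  sp <- small_spec(rng_seed = 55, n_patients = 8, n_subjects = 2)
  st <- simulate_study(sp, modalities = c(tms_a = "tms_scalp",
                                          lesion_a = "lesion"), n_dbs = 6)
  dir <- file.path(tempdir(), "study_out")
  on.exit(unlink(dir, recursive = TRUE))
  files <- write_study(st, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$rng_seed, 55L)
  expect_true(all(file.exists(file.path(dir, vapply(man$files, `[[`, "", "path")))))
  # checksums are reproducible: writing the same study again matches
  dir2 <- file.path(tempdir(), "study_out2")
  on.exit(unlink(dir2, recursive = TRUE), add = TRUE)
  write_study(st, dir2)
  md5a <- vapply(man$files, `[[`, "", "md5")
  man2 <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  expect_equal(md5a, vapply(man2$files, `[[`, "", "md5"))
  # the circuit NIfTI reads back onto the same grid with the same values
  back <- read_volume(file.path(dir, "circuit.nii.gz"))
  expect_true(grids_equal(back$grid, st$grid))
  m <- st$circuit$brain_mask
  expect_lt(max(abs(back$data[m] - st$circuit$data[m])), 1e-6)
  # cohort CSV re-reads with the recorded outcomes
  tab <- read.csv(file.path(dir, "cohort_tms_a.csv"))
  expect_equal(tab$anxiety,
               vapply(st$datasets$tms_a$records, `[[`, numeric(1), "anxiety"))
})
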