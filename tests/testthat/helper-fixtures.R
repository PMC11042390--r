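# Shared in-code fixtures: tiny grids, toy connectomes, and cohorts built
# directly from Fisher-z matrices so statistical machinery can be tested
# without running the full generator.

mm_grid <- function(shape = c(8, 8, 8), voxel = 1) {
  aff <- diag(c(voxel, voxel, voxel, 1))
  brain_grid(shape, aff)
}

centered_grid <- function(shape = c(8, 8, 8), voxel = 2) {
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- -(shape - 1) / 2 * voxel
  brain_grid(shape, aff)
}

# cohort whose records carry prescribed zmaps and outcomes; sites are
# single-voxel lesions (unused by the map machinery under test)
toy_cohort <- function(Z, y, depression, grid, mask, name = "toy",
                       modality = "lesion", extras = NULL) {
  n <- nrow(Z)
  site_mask <- array(0, grid$shape)
  site_mask[which(mask)[1]] <- 1
  site <- lesion_site(brain_volume(grid, site_mask))
  records <- lapply(seq_len(n), function(i) {
    zv <- volume_from_mask(grid, mask, Z[i, ])
    cm <- structure(list(zmap = zv, site = site, n_subjects_used = 1L),
                    class = "connectivity_map")
    ex <- if (is.null(extras)) list() else lapply(extras, `[`, i)
    patient_record(sprintf("p%03d", i), site, anxiety = y[i],
                   depression = depression[i], conn_map = cm,
                   extra_covariates = ex)
  })
  cohort_dataset(name, modality, records)
}

# clone a cohort with fresh outcomes (the beta = 0 generative model), used
# by the calibration tests so sites and imaging stay fixed across replicates
with_null_outcomes <- function(dataset, seed) {
  set.seed(seed)
  n <- dataset$n
  y <- rnorm(n); d <- rnorm(n)
  records <- lapply(seq_len(n), function(i) {
    r <- dataset$records[[i]]
    patient_record(r$id, r$site, anxiety = y[i], depression = d[i],
                   conn_map = r$conn_map, extra_covariates = r$extra_covariates)
  })
  cohort_dataset(dataset$name, dataset$modality, records)
}

# brute-force partial correlation from the precision matrix of [x, y, C]
pcor_oracle <- function(x, y, C = NULL) {
  M <- cbind(x, y, C)
  P <- solve(stats::cov(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# small factor-model connectome with known voxel-voxel correlations:
# x_v = a_v * f + sqrt(1 - a_v^2) * e_v, so cor(x_u, x_v) = a_u * a_v
factor_connectome <- function(grid, mask, loadings, n_subjects, n_timepoints,
                              seed) {
  set.seed(seed)
  V <- sum(mask)
  stopifnot(length(loadings) == V)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    f <- rnorm(n_timepoints)
    E <- matrix(rnorm(n_timepoints * V), n_timepoints, V)
    sweep(E, 2, sqrt(1 - loadings^2), `*`) + outer(f, loadings)
  })
  connectome_dataset(grid, mask, subjects)
}

single_voxel_site <- function(grid, mask, lin_idx) {
  m <- array(0, grid$shape)
  m[lin_idx] <- 1
  lesion_site(brain_volume(grid, m, mask))
}
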