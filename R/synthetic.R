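#' Specification of a synthetic study
#'
#' The stated world for desk-scale testing: a 16^3 toy brain (2 mm voxels,
#' spherical mask), a planted two-pole circuit, a multi-subject connectome
#' with Gaussian spatial autocorrelation and shared latent components on
#' the circuit poles, and cohorts whose anxiety outcome is driven by
#' site-circuit connectivity with a depression confound targeting the
#' pooled anxiety-depression correlation of 0.53.
#'
#' @param grid_shape integer triple (default 16^3).
#' @param voxel_size_mm isotropic voxel size in mm (default 2).
#' @param n_subjects connectome subjects (default 20).
#' @param n_timepoints timepoints per subject (default 100, minimum 32).
#' @param smoothness_mm sd (mm) of the Gaussian spatial-autocorrelation
#'   kernel of the noise field (default 4; 0 = white noise).
#' @param circuit_peaks list of `list(center_mm, sign, width_mm)`; default
#'   one positive and one negative Gaussian pole (width = sd in mm).
#' @param latent_strength amplitude of the shared circuit latent relative
#'   to unit-variance noise (default 1).
#' @param effect_beta site-to-anxiety effect on the standardized true score
#'   (default 0.5).
#' @param confound_rho target anxiety-depression correlation (default 0.53,
#'   the pooled value the generator emulates).
#' @param noise_sigma sd of the outcome noise (default 1).
#' @param n_patients cohort size (default 100).
#' @param modality default cohort modality.
#' @param rng_seed master seed; every stage derives child seeds from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(grid_shape = c(16L, 16L, 16L),
                           voxel_size_mm = 2,
                           n_subjects = 20L,
                           n_timepoints = 100L,
                           smoothness_mm = 4,
                           circuit_peaks = NULL,
                           latent_strength = 1,
                           effect_beta = 0.5,
                           confound_rho = 0.53,
                           noise_sigma = 1,
                           n_patients = 100L,
                           modality = "lesion",
                           rng_seed = 1L) {
  stopifnot(n_timepoints >= 32L, n_subjects >= 1L, noise_sigma > 0,
            abs(confound_rho) < 1)
  half <- (grid_shape - 1) / 2 * voxel_size_mm
  if (is.null(circuit_peaks)) {
    circuit_peaks <- list(
      list(center_mm = c(0.4, 0.4, 0.4) * half, sign = 1, width_mm = 6),
      list(center_mm = -c(0.4, 0.4, 0.4) * half, sign = -1, width_mm = 6))
  }
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_mm = voxel_size_mm,
               n_subjects = as.integer(n_subjects),
               n_timepoints = as.integer(n_timepoints),
               smoothness_mm = smoothness_mm,
               circuit_peaks = circuit_peaks,
               latent_strength = latent_strength,
               effect_beta = effect_beta,
               confound_rho = confound_rho,
               noise_sigma = noise_sigma,
               n_patients = as.integer(n_patients),
               modality = modality,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "synthetic_spec"
  spec
}

#' Grid and spherical brain mask of a synthetic spec
#'
#' The affine is diagonal with the world origin at the grid centre; the
#' brain mask is the sphere covering 95% of the half-extent.
#'
#' @param spec a [synthetic_spec()].
#' @return list(grid, mask) with `mask` a logical array.
#' @export
synthetic_grid <- function(spec) {
  vs <- spec$voxel_size_mm
  origin <- -(spec$grid_shape - 1) / 2 * vs
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- origin
  grid <- brain_grid(spec$grid_shape, affine)
  xyz <- voxel_world_coords(grid, seq_len(prod(grid$shape)))
  radius <- 0.95 * min((spec$grid_shape - 1) / 2 * vs)
  mask <- array(sqrt(rowSums(xyz^2)) <= radius, dim = grid$shape)
  list(grid = grid, mask = mask, radius_mm = radius)
}

#' Planted ground-truth circuit
#'
#' Sum of signed Gaussian bumps at the spec's peaks, normalized so the
#' maximum absolute value is 1. Serves as the recovery target for every
#' parameter-recovery and calibration test.
#'
#' @param spec a [synthetic_spec()].
#' @return A [brain_volume()], NA outside the brain mask.
#' @export
make_circuit <- function(spec) {
  stopifnot(length(spec$circuit_peaks) >= 1L)
  gm <- synthetic_grid(spec)
  xyz <- voxel_world_coords(gm$grid, seq_len(prod(gm$grid$shape)))
  vals <- numeric(nrow(xyz))
  for (pk in spec$circuit_peaks) {
    vox <- world_to_voxel(gm$grid, pk$center_mm)
    if (any(vox < 0) || any(vox > gm$grid$shape - 1))
      stop("circuit peak lies outside the grid")
    d2 <- rowSums((xyz - matrix(pk$center_mm, nrow(xyz), 3, byrow = TRUE))^2)
    vals <- vals + pk$sign * exp(-d2 / (2 * pk$width_mm^2))
  }
  vals <- vals / max(abs(vals))
  volume_from_mask(gm$grid, gm$mask, vals[gm$mask])
}

# smoothing machinery shared by the generator and the analytic fingerprints:
# axis convolution matrices for the noise kernel and the per-voxel sd of
# smoothed-unit-white-noise (so normalized noise has unit variance even at
# the mask edge)
noise_operator <- function(spec) {
  sig_vox <- spec$smoothness_mm / spec$voxel_size_mm
  k <- gaussian_axis_kernel(sig_vox)
  Ks <- lapply(spec$grid_shape, conv_matrix, kernel = k)
  Ks2 <- lapply(spec$grid_shape, conv_matrix, kernel = k^2)
  ones <- matrix(1, prod(spec$grid_shape), 1)
  sd_loc <- sqrt(smooth_stack(ones, spec$grid_shape, Ks2)[, 1])
  list(Ks = Ks, sd_loc = sd_loc)
}

#' Synthetic multi-subject connectome
#'
#' Per subject, each voxel's time-series is spatially smoothed white noise
#' (normalized to unit variance voxel-wise) plus a shared latent component
#' loading on the planted circuit: loading `latent_strength * circuit(v)`,
#' so the positive and negative poles are anticorrelated and seed maps from
#' circuit-adjacent sites resemble the circuit. Deterministic given the
#' spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param circuit optional planted circuit ([brain_volume()]); default
#'   [make_circuit()] of the spec. Pass NULL explicitly via
#'   `latent_strength = 0` semantics by setting no peaks is not supported;
#'   set `latent_strength = 0` for a latent-free connectome.
#' @return A [connectome_dataset()].
#' @export
make_connectome <- function(spec, circuit = NULL) {
  if (is.null(circuit)) circuit <- make_circuit(spec)
  gm <- synthetic_grid(spec)
  nop <- noise_operator(spec)
  load_full <- circuit$data
  load_full[!is.finite(load_full)] <- 0
  loading <- spec$latent_strength * as.vector(load_full)
  Tn <- spec$n_timepoints
  npix <- prod(spec$grid_shape)
  seeds <- child_seeds(spec$rng_seed, spec$n_subjects)
  V <- sum(gm$mask)
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    old <- local_seed(seeds[s])
    g <- stats::rnorm(Tn)
    E <- matrix(stats::rnorm(npix * Tn), npix, Tn)
    restore_seed(old)
    E <- smooth_stack(E, spec$grid_shape, nop$Ks) / nop$sd_loc
    X <- E + outer(loading, g)
    subjects[[s]] <- t(X[gm$mask, , drop = FALSE])
  }
  connectome_dataset(gm$grid, gm$mask, subjects)
}

# Analytic (noiseless) connectivity fingerprints of seed sites under the
# generator's covariance model. W: V x n matrix of normalized site weights
# over the mask. Returns an n x V matrix of Fisher-z fingerprints.
# Separating this generative truth from finite-sample seed maps is what
# makes recovery targets meaningful.
analytic_fingerprints <- function(spec, circuit, W) {
  gm <- synthetic_grid(spec)
  nop <- noise_operator(spec)
  load_full <- circuit$data
  load_full[!is.finite(load_full)] <- 0
  lam <- spec$latent_strength * as.vector(load_full)   # latent loading per voxel
  n <- ncol(W)
  npix <- prod(spec$grid_shape)
  Wf <- matrix(0, npix, n)
  Wf[gm$mask, ] <- W
  # noise covariance: C_e = D^-1 S S D^-1 with S the symmetric smoothing
  # operator and D = diag(sd_loc); q = C_e w and the seed noise variance is
  # ||S D^-1 w||^2
  SDw <- smooth_stack(Wf / nop$sd_loc, spec$grid_shape, nop$Ks)
  q <- smooth_stack(SDw, spec$grid_shape, nop$Ks) / nop$sd_loc
  noise_var_seed <- colSums(SDw^2)
  L <- as.vector(crossprod(Wf, lam))                   # latent loading of each seed
  var_seed <- L^2 + noise_var_seed
  var_vox <- lam^2 + 1
  Z <- matrix(0, n, sum(gm$mask))
  mvox <- which(gm$mask)
  for (i in seq_len(n)) {
    cov_i <- lam[mvox] * L[i] + q[mvox, i]
    r <- cov_i / sqrt(var_seed[i] * var_vox[mvox])
    Z[i, ] <- atanh(clip_r(r))
  }
  Z
}

# --- site placement ---------------------------------------------------------

# binary blob volume: the k in-mask voxels nearest (world mm) to a centre
blob_volume <- function(grid, mask, center_mm, k) {
  idx <- which(mask)
  xyz <- voxel_world_coords(grid, idx)
  d <- sqrt(rowSums((xyz - matrix(center_mm, nrow(xyz), 3, byrow = TRUE))^2))
  sel <- idx[order(d)[seq_len(k)]]
  data <- array(0, dim = grid$shape)
  data[sel] <- 1
  brain_volume(grid, data, mask)
}

# in-mask voxels with an out-of-mask 6-neighbour: the "cortical shell"
shell_voxels <- function(mask, shape) {
  pad <- function(sh) {
    m <- array(FALSE, dim = shape + 2L)
    m[2:(shape[1] + 1), 2:(shape[2] + 1), 2:(shape[3] + 1)] <- mask
    m
  }
  mp <- pad(shape)
  core <- mp[2:(shape[1] + 1), 2:(shape[2] + 1), 2:(shape[3] + 1)]
  nb_all <- mp[1:shape[1], 2:(shape[2] + 1), 2:(shape[3] + 1)] &
    mp[3:(shape[1] + 2), 2:(shape[2] + 1), 2:(shape[3] + 1)] &
    mp[2:(shape[1] + 1), 1:shape[2], 2:(shape[3] + 1)] &
    mp[2:(shape[1] + 1), 3:(shape[2] + 2), 2:(shape[3] + 1)] &
    mp[2:(shape[1] + 1), 2:(shape[2] + 1), 1:shape[3]] &
    mp[2:(shape[1] + 1), 2:(shape[2] + 1), 3:(shape[3] + 2)]
  which(core & !nb_all)
}

random_sites <- function(spec, modality, n, gm, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  grid <- gm$grid; mask <- gm$mask
  in_idx <- which(mask)
  xyz_in <- voxel_world_coords(grid, in_idx)
  if (modality == "lesion") {
    lapply(seq_len(n), function(i) {
      c_idx <- sample(length(in_idx), 1L)
      k <- sample(3:10, 1L)
      lesion_site(blob_volume(grid, mask, xyz_in[c_idx, ], k))
    })
  } else if (modality %in% c("tms_scalp", "tms_individualized")) {
    shell <- shell_voxels(mask, grid$shape)
    xyz_shell <- voxel_world_coords(grid, shell)
    lapply(seq_len(n), function(i) {
      ctr <- xyz_shell[sample(nrow(xyz_shell), 1L), ]
      tms_site(grid, ctr, max_radius_mm = 12)
    })
  } else if (modality == "dbs") {
    deep <- in_idx[sqrt(rowSums(xyz_in^2)) < 0.4 * gm$radius_mm &
                     xyz_in[, 1] > 0.5]
    xyz_deep <- voxel_world_coords(grid, deep)
    lapply(seq_len(n), function(i) {
      p <- xyz_deep[sample(nrow(xyz_deep), 1L), ]
      k <- sample(2:4, 1L)
      right <- blob_volume(grid, mask, p, k)
      left <- blob_volume(grid, mask, p * c(-1, 1, 1), k)
      dbs_pair_site(left, right)
    })
  } else stop("unknown modality: ", modality)
}

#' Synthetic cohort with confounded outcomes
#'
#' Places sites uniformly at random in the toy brain (lesions: 3-10-voxel
#' blobs; TMS: decaying spheres centred on the cortical shell; DBS:
#' mirrored deep field pairs of 2-4 voxels), computes each site's true
#' circuit score (spatial correlation of its analytic connectivity
#' fingerprint with the planted circuit for lesions/TMS; true field overlap
#' for DBS), and draws outcomes from the causal model
#'
#'   anxiety_i = effect_beta * s_i + gamma * d_i + noise_sigma * eps_i
#'
#' with s_i the standardized true score, d_i ~ N(0,1) the latent depression
#' confound (recorded as the depression score), and gamma solved so that
#' corr(anxiety, depression) equals `confound_rho` in expectation. Site
#' placement is independent of pre-existing outcome, mirroring the
#' as-if-random lesion assumption. Stimulation cohorts get an independent
#' baseline-severity covariate; lesion records carry lesion size.
#'
#' @param spec a [synthetic_spec()].
#' @param circuit planted circuit (default [make_circuit()]).
#' @param connectome a [connectome_dataset()] from [make_connectome()];
#'   needed for lesion/TMS cohorts (finite-sample seed maps). May be NULL
#'   for DBS cohorts.
#' @param name dataset name.
#' @param modality overrides `spec$modality`.
#' @param n overrides `spec$n_patients`.
#' @param rng_seed overrides the cohort-stage child seed.
#' @param compute_conn attach finite-sample connectivity maps (default TRUE
#'   for non-DBS modalities).
#' @return A [cohort_dataset()] whose records carry sites, outcomes,
#'   covariates, connectivity maps, and a `true_score` extra covariate.
#' @export
make_cohort <- function(spec, circuit = NULL, connectome = NULL,
                        name = "synthetic", modality = spec$modality,
                        n = spec$n_patients, rng_seed = NULL,
                        compute_conn = modality != "dbs") {
  if (is.null(circuit)) circuit <- make_circuit(spec)
  gm <- synthetic_grid(spec)
  if (sum(gm$mask) < 50L) stop("in-mask region too small for cohort simulation")
  seeds <- child_seeds(if (is.null(rng_seed)) spec$rng_seed + 1L else rng_seed, 3L)
  sites <- random_sites(spec, modality, n, gm, seeds[1])

  if (modality == "dbs") {
    s_raw <- vapply(sites, function(st) {
      dbs_overlap_score(st, circuit)$score
    }, numeric(1))
  } else {
    W <- vapply(sites, site_seed_weights, numeric(sum(gm$mask)),
                mask_arr = gm$mask)
    Zf <- analytic_fingerprints(spec, circuit, W)
    cvals <- circuit$data[gm$mask]
    s_raw <- as.vector(stats::cor(t(Zf), cvals))
  }
  s_std <- if (stats::sd(s_raw) > 0) as.vector(scale(s_raw)) else s_raw * 0

  old <- local_seed(seeds[2])
  d <- stats::rnorm(n)
  eps <- stats::rnorm(n)
  baseline <- stats::rnorm(n)
  baseline_dep <- stats::rnorm(n)
  restore_seed(old)

  beta <- spec$effect_beta; rho <- spec$confound_rho; sig <- spec$noise_sigma
  gamma <- sign(rho) * sqrt(rho^2 * (beta^2 + sig^2) / (1 - rho^2))
  anxiety <- beta * s_std + gamma * d + sig * eps
  depression <- d

  conn_maps <- if (compute_conn) {
    if (is.null(connectome)) stop("connectome required to compute connectivity maps")
    Z <- seed_connectivity_matrix(sites, connectome)
    lapply(seq_len(n), function(i) {
      structure(list(zmap = volume_from_mask(connectome$grid,
                                             connectome$brain_mask, Z[i, ]),
                     site = sites[[i]],
                     n_subjects_used = length(connectome$subjects)),
                class = "connectivity_map")
    })
  } else NULL

  records <- lapply(seq_len(n), function(i) {
    extras <- list(true_score = s_std[i])
    if (modality %in% c("tms_scalp", "tms_individualized"))
      extras$baseline <- baseline[i]
    if (modality == "dbs") {
      extras$baseline <- baseline[i]
      extras$baseline_depression <- baseline_dep[i]
    }
    patient_record(id = sprintf("%s_%03d", name, i), site = sites[[i]],
                   anxiety = anxiety[i], depression = depression[i],
                   conn_map = if (is.null(conn_maps)) NULL else conn_maps[[i]],
                   extra_covariates = extras)
  })
  cohort_dataset(name, modality, records)
}

#' Simulate a complete multi-cohort study
#'
#' One call builds the connectome, the planted circuit, the training
#' cohorts (default two scalp-TMS and two lesion cohorts, emulating the
#' four-dataset normative design), and a held-out DBS cohort for external
#' validation.
#'
#' @param spec a [synthetic_spec()].
#' @param modalities training cohort modalities (named vector; names become
#'   dataset names).
#' @param n_dbs held-out DBS cohort size (default 74; 0 to skip).
#' @return list(spec, grid, mask, circuit, connectome, datasets, dbs).
#' @export
simulate_study <- function(spec,
                           modalities = c(tms_a = "tms_scalp",
                                          tms_b = "tms_scalp",
                                          lesion_a = "lesion",
                                          lesion_b = "lesion"),
                           n_dbs = 74L) {
  gm <- synthetic_grid(spec)
  circuit <- make_circuit(spec)
  connectome <- make_connectome(spec, circuit)
  seeds <- child_seeds(spec$rng_seed + 2L, length(modalities) + 1L)
  datasets <- vector("list", length(modalities))
  for (i in seq_along(modalities)) {
    datasets[[i]] <- make_cohort(spec, circuit, connectome,
                                 name = names(modalities)[i],
                                 modality = modalities[[i]],
                                 rng_seed = seeds[i])
  }
  names(datasets) <- names(modalities)
  dbs <- if (n_dbs > 0L)
    make_cohort(spec, circuit, connectome = NULL, name = "dbs_holdout",
                modality = "dbs", n = n_dbs, rng_seed = seeds[length(seeds)],
                compute_conn = FALSE)
  else NULL
  list(spec = spec, grid = gm$grid, mask = gm$mask, circuit = circuit,
       connectome = connectome, datasets = datasets, dbs = dbs)
}

#' Write a simulated study to disk
#'
#' Emits the circuit and brain mask as NIfTI, each cohort's table as CSV,
#' each connectome subject as 4-D NIfTI, and a JSON manifest recording the
#' spec, seed, and an md5 checksum per file, so reruns with one seed are
#' verifiably identical.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if missing).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "circuit.nii.gz")
  write_volume(study$circuit, p); paths <- c(paths, p)
  maskvol <- brain_volume(study$grid, array(as.numeric(study$mask),
                                            study$grid$shape))
  p <- file.path(dir, "brain_mask.nii.gz")
  write_volume(maskvol, p, dtype = "uint8"); paths <- c(paths, p)
  for (i in seq_along(study$connectome$subjects)) {
    ts <- study$connectome$subjects[[i]]
    arr <- array(0, c(study$grid$shape, nrow(ts)))
    flat <- matrix(arr, prod(study$grid$shape), nrow(ts))
    flat[study$connectome$mask_idx, ] <- t(ts)
    p <- file.path(dir, sprintf("connectome_sub%02d.nii.gz", i))
    write_timeseries(array(flat, c(study$grid$shape, nrow(ts))), study$grid, p)
    paths <- c(paths, p)
  }
  all_cohorts <- c(study$datasets, if (!is.null(study$dbs)) list(dbs = study$dbs))
  for (ds in all_cohorts) {
    p <- file.path(dir, paste0("cohort_", ds$name, ".csv"))
    write_cohort_csv(ds, p); paths <- c(paths, p)
  }
  manifest <- list(
    rng_seed = study$spec$rng_seed,
    spec = study$spec[setdiff(names(study$spec), "circuit_peaks")],
    files = lapply(paths, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, "manifest.json")))
}
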