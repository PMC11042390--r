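#' Connectome dataset
#'
#' A set of resting-state subjects sharing one grid and brain mask. Each
#' subject is stored as a T x V matrix of time-series over the in-mask
#' voxels (V = number of TRUE voxels in `brain_mask`, column order =
#' `which(brain_mask)`), the layout every seed operation works on.
#'
#' @param grid a [brain_grid()].
#' @param brain_mask logical array on `grid$shape`.
#' @param subjects list of T_s x V numeric matrices (T_s may differ across
#'   subjects, each at least 8 timepoints).
#' @return An object of class `connectome_dataset` with fields `grid`,
#'   `brain_mask`, `mask_idx` (linear voxel indices of columns), `subjects`.
#' @export
connectome_dataset <- function(grid, brain_mask, subjects) {
  brain_mask <- array(as.logical(brain_mask), dim = grid$shape)
  if (!any(brain_mask)) stop("empty brain mask")
  V <- sum(brain_mask)
  stopifnot(length(subjects) >= 1L)
  for (i in seq_along(subjects)) {
    m <- subjects[[i]]
    if (!is.matrix(m) || ncol(m) != V)
      stop(sprintf("subject %d: expected a T x %d matrix", i, V))
    if (nrow(m) < 8L) stop(sprintf("subject %d: fewer than 8 timepoints", i))
    if (!all(is.finite(m))) stop(sprintf("subject %d: non-finite time-series", i))
  }
  structure(list(grid = grid, brain_mask = brain_mask,
                 mask_idx = which(brain_mask), subjects = subjects),
            class = "connectome_dataset")
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat("connectome_dataset:", length(x$subjects), "subjects,",
      length(x$mask_idx), "in-mask voxels,",
      nrow(x$subjects[[1]]), "timepoints (first subject)\n")
  invisible(x)
}

#' Load a connectome from 4-D NIfTI time-series files
#'
#' @param paths one 4-D NIfTI per subject, all on one grid.
#' @param brain_mask a binary [brain_volume()] bounding the analysis.
#' @export
connectome_from_nifti <- function(paths, brain_mask) {
  grid <- brain_mask$grid
  m <- brain_mask$brain_mask & brain_mask$data != 0
  subjects <- lapply(paths, function(p) {
    ts <- read_timeseries(p)
    stop_if_grid_mismatch(ts$grid, grid, "connectome subject and mask")
    d <- dim(ts$data)
    t(matrix(ts$data, prod(d[1:3]), d[4])[m, , drop = FALSE])
  })
  connectome_dataset(grid, m, subjects)
}

clip_r <- function(r, eps = 1e-7) pmin(pmax(r, -(1 - eps)), 1 - eps)

#' Seed time-course of a stimulation site in one subject
#'
#' The weight-weighted mean time-series over in-mask voxels with positive
#' site weight (weights normalized to sum 1 over those voxels).
#'
#' @param site a `stimulation_site` (not a DBS pair).
#' @param subject_ts T x V matrix of in-mask time-series (a
#'   `connectome_dataset` subject).
#' @param brain_mask logical array giving the column layout of `subject_ts`.
#' @return Numeric vector of length T.
#' @export
seed_timecourse <- function(site, subject_ts, brain_mask) {
  w <- site_seed_weights(site, brain_mask)
  as.vector(subject_ts %*% w)
}

#' Whole-brain seed connectivity of a site
#'
#' For each subject: Pearson r between the site's seed time-course and every
#' in-mask voxel's time-series, clipped to +/-(1 - 1e-7), Fisher-z
#' transformed (atanh), then averaged across subjects. This is the standard
#' normative-connectome estimate of a perturbation's network; with a single
#' subject it is the individualized estimate.
#'
#' Subjects whose seed time-course has zero variance are skipped with a
#' warning; it is an error if all are skipped. DBS pairs are rejected:
#' bilateral fields cannot be a single seed and are scored by overlap
#' instead.
#'
#' @param site a `stimulation_site` of kind "lesion" or "tms".
#' @param connectome a [connectome_dataset()].
#' @return An object of class `connectivity_map`: fields `zmap`
#'   ([brain_volume()] of mean Fisher-z), `site`, `n_subjects_used`.
#' @export
seed_connectivity <- function(site, connectome) {
  if (site$kind == "dbs_pair")
    stop("seed connectivity is undefined for bilateral DBS pairs; use overlap scoring")
  stop_if_grid_mismatch(site$weights$grid, connectome$grid, "site and connectome")
  V <- length(connectome$mask_idx)
  zsum <- numeric(V)
  used <- 0L
  for (s in seq_along(connectome$subjects)) {
    ts <- connectome$subjects[[s]]
    seed <- seed_timecourse(site, ts, connectome$brain_mask)
    if (stats::sd(seed) < .Machine$double.eps^0.5) {
      warning(sprintf("subject %d: zero-variance seed time-course, skipped", s))
      next
    }
    r <- suppressWarnings(as.vector(stats::cor(seed, ts)))
    r[!is.finite(r)] <- 0  # zero-variance voxels carry no signal
    zsum <- zsum + atanh(clip_r(r))
    used <- used + 1L
  }
  if (used == 0L) stop("all subjects skipped: no usable seed time-course")
  zmap <- volume_from_mask(connectome$grid, connectome$brain_mask, zsum / used)
  structure(list(zmap = zmap, site = site, n_subjects_used = used),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat("connectivity_map (mean Fisher-z over", x$n_subjects_used, "subjects)\n")
  print(x$zmap)
  invisible(x)
}

# Batch seed maps for many sites against one connectome: returns an
# n_sites x V matrix of mean Fisher-z. Same math as seed_connectivity but
# one matrix product per subject, used by the synthetic cohorts.
seed_connectivity_matrix <- function(sites, connectome) {
  V <- length(connectome$mask_idx)
  W <- vapply(sites, site_seed_weights, numeric(V),
              mask_arr = connectome$brain_mask)   # V x n
  n <- length(sites)
  Z <- matrix(0, n, V)
  for (ts in connectome$subjects) {
    seeds <- ts %*% W                              # T x n
    r <- suppressWarnings(stats::cor(seeds, ts))   # n x V
    r[!is.finite(r)] <- 0
    Z <- Z + atanh(clip_r(r))
  }
  Z / length(connectome$subjects)
}

# mean pairwise Fisher-z between two column sets of one subject's
# time-series; cols_a == cols_b gives the within-set mean over distinct pairs
mean_pairwise_z <- function(ts, cols_a, cols_b, within = FALSE) {
  r <- suppressWarnings(stats::cor(ts[, cols_a, drop = FALSE],
                                   ts[, cols_b, drop = FALSE]))
  r[!is.finite(r)] <- 0
  z <- atanh(clip_r(r))
  if (within) {
    if (length(cols_a) < 2L) stop("fewer than 2 voxels in a pole/network")
    mean(z[upper.tri(z)])
  } else {
    mean(z)
  }
}

subsample_cols <- function(cols, max_n, rng) {
  if (length(cols) <= max_n) return(cols)
  sort(cols[sample.int(length(cols), max_n)])
}

#' Within-circuit connectivity of one subject
#'
#' Scores how strongly a subject's own resting-state data expresses a
#' circuit's anticorrelated organisation. Let P be the top `top_fraction`
#' of positive-valued circuit voxels and N the top `top_fraction` most
#' negative. The score is mean pairwise Fisher-z within P, plus within N,
#' minus between P and N; pairwise means are computed over a seeded uniform
#' subsample of at most `max_voxels` voxels per pole so cost is bounded.
#'
#' @param circuit a [brain_volume()] with both positive and negative values.
#' @param subject_ts T x V in-mask time-series matrix.
#' @param brain_mask logical array giving the column layout of `subject_ts`.
#' @param top_fraction fraction of each pole's voxels used (default 0.10).
#' @param max_voxels subsampling cap per pole (default 500).
#' @param rng_seed seed for the subsample.
#' @return A scalar score; symmetric under negation of the circuit map.
#' @export
within_circuit_connectivity <- function(circuit, subject_ts, brain_mask,
                                        top_fraction = 0.10, max_voxels = 500L,
                                        rng_seed = 1L) {
  force(subject_ts)  # evaluate caller data before touching the RNG
  stopifnot(top_fraction > 0, top_fraction <= 1)
  vals <- circuit$data[brain_mask]
  vals[!circuit$brain_mask[brain_mask]] <- NA_real_
  pos <- which(vals > 0 & is.finite(vals))
  neg <- which(vals < 0 & is.finite(vals))
  if (length(pos) == 0L || length(neg) == 0L)
    stop("circuit must have both positive and negative in-mask voxels")
  npos <- max(2L, ceiling(top_fraction * length(pos)))
  nneg <- max(2L, ceiling(top_fraction * length(neg)))
  if (length(pos) < 2L || length(neg) < 2L)
    stop("fewer than 2 voxels in a pole")
  P <- pos[order(vals[pos], decreasing = TRUE)[seq_len(min(npos, length(pos)))]]
  N <- neg[order(vals[neg])[seq_len(min(nneg, length(neg)))]]
  old <- local_seed(rng_seed)
  on.exit(restore_seed(old))
  P <- subsample_cols(P, max_voxels)
  N <- subsample_cols(N, max_voxels)
  mean_pairwise_z(subject_ts, P, P, within = TRUE) +
    mean_pairwise_z(subject_ts, N, N, within = TRUE) -
    mean_pairwise_z(subject_ts, P, N)
}

#' Within/between connectivity scores for control networks
#'
#' For each unordered pair of networks (including self-pairs) in an integer
#' label volume, the mean pairwise Fisher-z between their voxels, with the
#' same per-network subsampling contract as
#' [within_circuit_connectivity()]. Seven networks yield 28 scores.
#'
#' @param subject_ts T x V in-mask time-series matrix.
#' @param network_labels integer vector of length V (0 = unlabelled).
#' @param max_voxels subsampling cap per network.
#' @param rng_seed seed for the subsample.
#' @return data.frame with columns `net_a`, `net_b`, `type`
#'   ("within"/"between"), `score`.
#' @export
control_network_scores <- function(subject_ts, network_labels,
                                   max_voxels = 500L, rng_seed = 1L) {
  force(subject_ts)  # evaluate caller data before touching the RNG
  labs <- sort(unique(network_labels[network_labels > 0]))
  if (length(labs) < 2L) stop("need at least 2 networks")
  cols <- lapply(labs, function(l) which(network_labels == l))
  sizes <- lengths(cols)
  if (any(sizes < 2L))
    stop(sprintf("network %d has fewer than 2 voxels", labs[which(sizes < 2L)[1]]))
  old <- local_seed(rng_seed)
  on.exit(restore_seed(old))
  cols <- lapply(cols, subsample_cols, max_n = max_voxels)
  out <- list()
  k <- 0L
  for (i in seq_along(labs)) for (j in i:length(labs)) {
    k <- k + 1L
    out[[k]] <- data.frame(
      net_a = labs[i], net_b = labs[j],
      type = if (i == j) "within" else "between",
      score = mean_pairwise_z(subject_ts, cols[[i]], cols[[j]], within = i == j))
  }
  do.call(rbind, out)
}
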