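#' Spatial correlation between two brain maps
#'
#' Pearson correlation over in-mask voxel values, the standard similarity
#' statistic for statistical brain maps. Accepts `brain_volume`s or
#' `circuit_map`s/`connectivity_map`s (their value volume is used).
#'
#' @param a,b maps on one grid.
#' @param mask optional extra mask (logical array or mask volume); the
#'   voxels used are the intersection of both maps' masks and `mask`.
#' @param min_voxels minimum in-mask voxel count (default 10).
#' @return Scalar Pearson r.
#' @export
spatial_correlation <- function(a, b, mask = NULL, min_voxels = 10L) {
  a <- as_value_volume(a); b <- as_value_volume(b)
  stop_if_grid_mismatch(a$grid, b$grid, "maps")
  m <- a$brain_mask & b$brain_mask
  if (!is.null(mask)) m <- m & resolve_mask(mask, a$grid)
  if (sum(m) < min_voxels) stop("mask too small for spatial correlation")
  va <- a$data[m]; vb <- b$data[m]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant map: spatial correlation undefined")
  stats::cor(va, vb)
}

as_value_volume <- function(x) {
  if (inherits(x, "brain_volume")) return(x)
  if (inherits(x, "circuit_map")) return(x$rmap)
  if (inherits(x, "connectivity_map")) return(x$zmap)
  stop("expected a brain_volume, circuit_map, or connectivity_map")
}

new_permutation_result <- function(observed, null_sample, n_permutations,
                                   rng_seed) {
  p <- (1 + sum(null_sample >= observed)) / (1 + n_permutations)
  structure(list(observed = observed, null_sample = null_sample,
                 p_value = p, n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$observed, x$p_value, x$n_permutations, x$rng_seed))
  invisible(x)
}

#' Serialize a permutation result to JSON
#'
#' @param x a `permutation_result`.
#' @param path output path.
#' @export
write_permutation_json <- function(x, path) {
  jsonlite::write_json(list(
    observed = x$observed, p_value = x$p_value,
    n_permutations = x$n_permutations, rng_seed = x$rng_seed,
    null_quantiles = as.list(stats::quantile(x$null_sample,
                                             c(0.025, 0.25, 0.5, 0.75, 0.975)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Precompute each dataset's design so the permutation loop is pure matrix
# work: per dataset a list(y, C, Z, weight, mask, grid). All datasets must
# share grid and end up on a common intersection mask.
perm_designs <- function(datasets, outcome_field, covariate_fields, mask) {
  designs <- lapply(datasets, function(ds) {
    cf <- if (is.list(covariate_fields)) covariate_fields[[ds$name]]
          else covariate_fields
    d <- cohort_design(ds, outcome_field, cf, mask)
    d$weight <- ds$n
    d$name <- ds$name
    d
  })
  g <- designs[[1]]$grid
  m <- designs[[1]]$mask
  for (d in designs) {
    stop_if_grid_mismatch(d$grid, g, "datasets")
    m <- m & d$mask
  }
  # restrict all Z to the common mask
  designs <- lapply(designs, function(d) {
    keep <- m[d$mask]
    d$Z <- d$Z[, keep, drop = FALSE]
    d$mask <- m
    d
  })
  attr(designs, "grid") <- g
  attr(designs, "mask") <- m
  designs
}

# combined weighted-mean r over mask for a set of designs, with the rows of
# (y, C) optionally permuted per dataset
combined_r <- function(designs, perms = NULL) {
  acc <- 0; wsum <- 0
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    idx <- if (is.null(perms)) seq_along(d$y) else perms[[i]]
    r <- pcor_map(d$Z, d$y[idx], d$C[idx, , drop = FALSE])
    acc <- acc + d$weight * r
    wsum <- wsum + d$weight
  }
  acc / wsum
}

shuffle_rows <- function(designs) {
  lapply(designs, function(d) sample.int(length(d$y)))
}

#' Outcome-shuffle permutation test for circuit-map similarity
#'
#' The convergence test between two groups of datasets (e.g. TMS vs
#' lesion): the observed statistic is the spatial correlation between the
#' two groups' combined circuit maps, and the null is built by randomly
#' re-assigning each patient's (outcome, covariates) tuple to a different
#' patient's neuroimaging within each dataset, rebuilding every circuit map,
#' recombining, and recomputing the correlation. The p-value is one-sided
#' ("stronger than chance") with the add-one correction
#' (1 + #\{null >= observed\}) / (1 + n_permutations).
#'
#' @param datasets list of [cohort_dataset()]s with connectivity maps.
#' @param split list with character vectors `a` and `b` naming the two
#'   groups of datasets.
#' @param n_permutations number of shuffles (default 10000).
#' @param rng_seed required integer seed; identical seeds give identical
#'   null samples.
#' @param outcome_field,covariate_fields,mask as in [circuit_map()];
#'   `covariate_fields` may be a named list keyed by dataset name.
#' @return A `permutation_result`.
#' @export
permutation_similarity_test <- function(datasets, split,
                                        n_permutations = 10000L, rng_seed,
                                        outcome_field = "anxiety",
                                        covariate_fields = NULL, mask = NULL) {
  stopifnot(n_permutations >= 1L)
  nms <- vapply(datasets, `[[`, character(1), "name")
  stopifnot(all(split$a %in% nms), all(split$b %in% nms))
  designs <- perm_designs(datasets, outcome_field, covariate_fields, mask)
  ia <- which(nms %in% split$a); ib <- which(nms %in% split$b)
  stat <- function(perms) {
    ra <- combined_r(designs[ia], if (is.null(perms)) NULL else perms[ia])
    rb <- combined_r(designs[ib], if (is.null(perms)) NULL else perms[ib])
    stats::cor(ra, rb)
  }
  run_permutations(designs, stat, n_permutations, rng_seed)
}

#' Mean cross-correlation permutation test over all dataset maps
#'
#' Robustness companion to [permutation_similarity_test()]: the observed
#' statistic is the mean spatial correlation over all unordered pairs of
#' per-dataset circuit maps, with the same shuffle-and-rebuild null.
#'
#' @inheritParams permutation_similarity_test
#' @export
mean_cross_correlation_test <- function(datasets, n_permutations = 10000L,
                                        rng_seed, outcome_field = "anxiety",
                                        covariate_fields = NULL, mask = NULL) {
  stopifnot(length(datasets) >= 2L, n_permutations >= 1L)
  designs <- perm_designs(datasets, outcome_field, covariate_fields, mask)
  pairs <- utils::combn(length(designs), 2)
  stat <- function(perms) {
    rs <- lapply(seq_along(designs), function(i) {
      d <- designs[[i]]
      idx <- if (is.null(perms)) seq_along(d$y) else perms[[i]]
      pcor_map(d$Z, d$y[idx], d$C[idx, , drop = FALSE])
    })
    mean(apply(pairs, 2, function(pr) stats::cor(rs[[pr[1]]], rs[[pr[2]]])))
  }
  run_permutations(designs, stat, n_permutations, rng_seed)
}

#' Max-statistic FWE test for a circuit peak
#'
#' Family-wise-error-corrected peak inference: the observed statistic is
#' the combined circuit value at the claimed peak voxel; each permutation
#' shuffles outcomes within datasets, rebuilds the combined map, and takes
#' its maximum in-mask voxel value (the max-statistic null that controls
#' FWE across voxels).
#'
#' @inheritParams permutation_similarity_test
#' @param peak_xyz_mm world coordinate of the claimed peak; must fall in the
#'   analysis mask.
#' @export
peak_fwe_test <- function(datasets, peak_xyz_mm, n_permutations = 10000L,
                          rng_seed, outcome_field = "anxiety",
                          covariate_fields = NULL, mask = NULL) {
  stopifnot(n_permutations >= 1L)
  designs <- perm_designs(datasets, outcome_field, covariate_fields, mask)
  g <- attr(designs, "grid"); m <- attr(designs, "mask")
  vox <- nearest_voxel(g, peak_xyz_mm)
  lin <- 1L + vox[1] + g$shape[1] * (vox[2] + g$shape[2] * vox[3])
  if (!m[lin]) stop("peak coordinate falls outside the analysis mask")
  pos <- sum(m[seq_len(lin)])  # column index of the peak within the mask
  stat_obs <- function(perms) combined_r(designs, perms)[pos]
  stat_null <- function(perms) max(combined_r(designs, perms))
  run_permutations(designs, stat_obs, n_permutations, rng_seed,
                   null_stat = stat_null)
}

run_permutations <- function(designs, stat, n_permutations, rng_seed,
                             null_stat = stat) {
  observed <- stat(NULL)
  old <- local_seed(rng_seed)
  on.exit(restore_seed(old))
  null_sample <- vapply(seq_len(n_permutations), function(b) {
    null_stat(shuffle_rows(designs))
  }, numeric(1))
  new_permutation_result(observed, null_sample, n_permutations, rng_seed)
}

#' Suprathreshold clusters and their centres of gravity
#'
#' Connected components (26-connectivity) of voxels strictly above
#' `threshold`, ranked by their maximum voxel value; for the top `k`
#' clusters, the value-weighted centre of gravity in world mm. A generic
#' stand-in for FSL-style cluster reporting.
#'
#' @param map a [brain_volume()] (or circuit map).
#' @param threshold voxels with value > threshold form clusters.
#' @param k number of clusters to report (fewer returned if fewer exist).
#' @return data.frame with columns `cog_x`, `cog_y`, `cog_z` (mm),
#'   `peak_value`, `cluster_size`.
#' @export
cluster_peaks <- function(map, threshold, k = 2L) {
  map <- as_value_volume(map)
  g <- map$grid
  above <- map$brain_mask & is.finite(map$data) & map$data > threshold
  if (!any(above)) stop("no voxel exceeds the threshold")
  labels <- label_components_26(above, g$shape)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  stats_per <- lapply(ids, function(id) {
    idx <- which(labels == id)
    vals <- map$data[idx]
    xyz <- voxel_world_coords(g, idx)
    w <- vals / sum(vals)
    cog <- colSums(xyz * w)
    data.frame(cog_x = cog[1], cog_y = cog[2], cog_z = cog[3],
               peak_value = max(vals), cluster_size = length(idx))
  })
  out <- do.call(rbind, stats_per)
  out <- out[order(-out$peak_value), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

# flood-fill labelling with 26-connectivity on a logical array
label_components_26 <- function(mask, shape) {
  labels <- array(0L, dim = shape)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  todo <- which(mask)
  nextlab <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- arrayInd(cur, shape)
      nb <- sweep(off, 2, as.integer(ijk), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
            nb[, 2] >= 1 & nb[, 2] <= shape[2] &
            nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + shape[1] * (nb[, 2] - 1L) + shape[1] * shape[2] * (nb[, 3] - 1L)
      lin <- lin[mask[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- nextlab
        queue <- c(queue, lin)
      }
    }
  }
  labels
}
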