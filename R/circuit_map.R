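#' Partial correlation via OLS residualization
#'
#' Pearson correlation of the residuals of `x` and `y` after ordinary
#' least-squares regression on an intercept plus `covariates`. This is the
#' voxel-level primitive of circuit mapping: at each voxel, the partial
#' correlation between site connectivity and outcome controlling for
#' nuisance variables. With a 0/1 `y` it is the point-biserial partial
#' correlation used for binarized-outcome analyses.
#'
#' @param x,y numeric vectors of equal length n.
#' @param covariates n x k numeric matrix (or NULL for a plain correlation).
#' @return Scalar in [-1, 1].
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) covariates <- matrix(numeric(0), n, 0L)
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  k <- ncol(covariates)
  if (n < k + 3L) stop(sprintf("n = %d too small for %d covariates", n, k))
  Q <- design_q(covariates)
  rx <- residualize(x, Q)
  ry <- residualize(y, Q)
  denom_x <- sum(rx^2); denom_y <- sum(ry^2)
  floor_x <- 1e-12 * max(sum((x - mean(x))^2), sum(x^2), 1)
  floor_y <- 1e-12 * max(sum((y - mean(y))^2), sum(y^2), 1)
  if (denom_x <= floor_x)
    stop("zero residual variance in x (degenerate/collinear)")
  if (denom_y <= floor_y)
    stop("zero residual variance in y (degenerate/collinear)")
  min(1, max(-1, sum(rx * ry) / sqrt(denom_x * denom_y)))
}

# thin Q of qr([1, C]); residualize() projects out its column space
design_q <- function(C) {
  X <- cbind(1, C)
  q <- qr(X)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

residualize <- function(v, Q) {
  if (is.matrix(v)) v - Q %*% crossprod(Q, v) else as.vector(v - Q %*% crossprod(Q, v))
}

# vectorized partial correlation of each column of Z against y given C;
# zero-residual-variance columns yield 0 (no signal), constant y errors
pcor_map <- function(Z, y, C) {
  Q <- design_q(C)
  ry <- residualize(y, Q)
  sy <- sum(ry^2)
  if (sy <= 1e-12 * max(sum((y - mean(y))^2), sum(y^2), 1))
    stop("outcome is constant (or collinear with covariates)")
  RZ <- residualize(Z, Q)
  sz <- colSums(RZ^2)
  r <- as.vector(crossprod(RZ, ry)) / sqrt(pmax(sz * sy, .Machine$double.xmin))
  r[sz <= .Machine$double.eps * nrow(Z)] <- 0
  pmin(1, pmax(-1, r))
}

#' Circuit map of one cohort
#'
#' At every in-mask voxel, the partial correlation across patients between
#' the Fisher-z connectivity value and the outcome, controlling for the
#' modality's nuisance covariates (see [default_covariates()]). The result
#' carries the dataset n as its combination weight.
#'
#' @param dataset a [cohort_dataset()] whose records have connectivity maps.
#' @param outcome_field outcome name (default "anxiety").
#' @param covariate_fields covariate names; NULL = modality defaults.
#' @param mask optional analysis mask (logical array or mask volume).
#' @return An object of class `circuit_map`: `rmap` ([brain_volume()] of
#'   partial r), `weight` (= dataset n), `provenance` (dataset names).
#' @export
circuit_map <- function(dataset, outcome_field = "anxiety",
                        covariate_fields = NULL, mask = NULL) {
  d <- cohort_design(dataset, outcome_field, covariate_fields, mask)
  if (length(d$y) < ncol(d$C) + 3L)
    stop(sprintf("dataset %s: %d complete records is too few for %d covariates",
                 dataset$name, length(d$y), ncol(d$C)))
  r <- pcor_map(d$Z, d$y, d$C)
  new_circuit_map(volume_from_mask(d$grid, d$mask, r),
                  weight = dataset$n, provenance = dataset$name)
}

new_circuit_map <- function(rmap, weight, provenance) {
  stopifnot(weight > 0)
  structure(list(rmap = rmap, weight = as.numeric(weight),
                 provenance = as.character(provenance)),
            class = "circuit_map")
}

#' @export
print.circuit_map <- function(x, ...) {
  cat("circuit_map [", paste(x$provenance, collapse = ", "),
      "] weight", x$weight, "\n")
  print(x$rmap)
  invisible(x)
}

#' Weighted mean of circuit maps
#'
#' Combines maps as sum(w_i * r_i) / sum(w_i) with w_i each map's weight
#' (dataset n); the combined weight is the summed n, so combination is
#' associative when intermediates are carried.
#'
#' @param maps list of `circuit_map`s on one grid.
#' @return A `circuit_map` with concatenated provenance.
#' @export
weighted_mean_map <- function(maps) {
  stopifnot(length(maps) >= 1L)
  g <- maps[[1]]$rmap$grid
  m <- maps[[1]]$rmap$brain_mask
  acc <- 0; wsum <- 0
  for (cm in maps) {
    stop_if_grid_mismatch(cm$rmap$grid, g, "circuit maps")
    m <- m & cm$rmap$brain_mask
    acc <- acc + cm$weight * cm$rmap$data
    wsum <- wsum + cm$weight
  }
  vals <- (acc / wsum)[m]
  new_circuit_map(volume_from_mask(g, m, vals), weight = wsum,
                  provenance = unlist(lapply(maps, `[[`, "provenance")))
}

#' Leave-one-dataset-out combined circuit
#'
#' Rebuilds the weighted-mean circuit from every dataset except the one
#' being predicted, keeping out-of-sample evaluation honest.
#'
#' @param datasets named list of [cohort_dataset()]s.
#' @param excluded name of the held-out dataset.
#' @param ... passed to [circuit_map()] (outcome, covariates, mask).
#' @export
leave_one_dataset_out <- function(datasets, excluded, ...) {
  nms <- vapply(datasets, `[[`, character(1), "name")
  if (!excluded %in% nms) stop(sprintf("no dataset named %s", excluded))
  rest <- datasets[nms != excluded]
  if (length(rest) == 0L) stop("no dataset remains after exclusion")
  weighted_mean_map(lapply(rest, circuit_map, ...))
}

#' Voxel lesion symptom mapping
#'
#' The classic comparator to connectivity-based mapping: at each voxel
#' lesioned in at least `min_lesions_per_voxel` patients, the partial
#' correlation between the binary lesioned indicator and the outcome given
#' the covariates. Voxels below the lesion-count threshold are masked out.
#'
#' @param dataset a lesion [cohort_dataset()].
#' @param outcome_field outcome name.
#' @param covariate_fields covariate names; NULL = lesion defaults.
#' @param min_lesions_per_voxel minimum lesion count per tested voxel.
#' @param mask optional analysis mask.
#' @return A [brain_volume()] of partial r, NA outside tested voxels.
#' @export
vlsm_map <- function(dataset, outcome_field = "anxiety",
                     covariate_fields = NULL, min_lesions_per_voxel = 5L,
                     mask = NULL) {
  if (dataset$modality != "lesion") stop("VLSM requires a lesion cohort")
  if (is.null(covariate_fields))
    covariate_fields <- default_covariates("lesion")
  recs <- dataset$records
  g <- site_grid(recs[[1]])
  m <- resolve_mask(mask, g)
  L <- t(vapply(recs, function(r) {
    w <- r$site$weights$data
    w[!r$site$weights$brain_mask] <- 0
    as.numeric(w[m] > 0)
  }, numeric(sum(m))))
  counts <- colSums(L)
  test <- counts >= min_lesions_per_voxel & counts <= nrow(L) - 1L
  if (!any(test)) stop("no voxel meets the minimum lesion count")
  y <- vapply(recs, record_field, numeric(1), field = outcome_field)
  C <- vapply(recs, function(r)
    vapply(covariate_fields, record_field, numeric(1), record = r),
    numeric(length(covariate_fields)))
  C <- matrix(C, nrow = length(recs), byrow = TRUE)
  r <- pcor_map(L[, test, drop = FALSE], y, C)
  full_mask <- array(FALSE, g$shape)
  full_mask[which(m)[test]] <- TRUE
  volume_from_mask(g, full_mask, r)
}
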