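#' Brain volume: a scalar field on a grid with an analysis mask
#'
#' The universal currency of the pipeline. `data` is a 3-D array on
#' `grid$shape`; `brain_mask` marks voxels eligible for analysis. Non-finite
#' data values are always forced outside the mask so correlations never see
#' NaN.
#'
#' @param grid a [brain_grid()].
#' @param data numeric array with `prod(grid$shape)` elements.
#' @param brain_mask logical array of the same shape, or NULL for
#'   "all finite voxels".
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(grid, data, brain_mask = NULL) {
  stopifnot(inherits(grid, "brain_grid"))
  data <- array(as.numeric(data), dim = grid$shape)
  if (is.null(brain_mask)) {
    brain_mask <- is.finite(data)
  } else {
    brain_mask <- array(as.logical(brain_mask), dim = grid$shape)
    brain_mask[is.na(brain_mask)] <- FALSE
    brain_mask <- brain_mask & is.finite(data)
  }
  if (!any(brain_mask)) stop("brain_mask leaves no analysable voxel")
  structure(list(grid = grid, data = data, brain_mask = brain_mask),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("brain_volume on", paste(x$grid$shape, collapse = "x"),
      "grid;", sum(x$brain_mask), "in-mask voxels; range",
      paste(signif(range(x$data[x$brain_mask]), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' In-mask values of a volume as a plain vector
#'
#' @param vol a `brain_volume`.
#' @param mask optional logical array overriding/intersecting the volume mask.
#' @export
mask_values <- function(vol, mask = NULL) {
  m <- vol$brain_mask
  if (!is.null(mask)) m <- m & resolve_mask(mask, vol$grid)
  vol$data[m]
}

# accept a brain_volume, logical array, or NULL as a mask
resolve_mask <- function(mask, grid) {
  if (is.null(mask)) return(array(TRUE, dim = grid$shape))
  if (inherits(mask, "brain_volume")) {
    stop_if_grid_mismatch(mask$grid, grid, "mask and volume")
    m <- mask$brain_mask & is.finite(mask$data) & mask$data != 0
    return(m)
  }
  array(as.logical(mask), dim = grid$shape)
}

#' Build a volume from values on in-mask voxels
#'
#' Inverse of [mask_values()]: places `values` at the TRUE positions of
#' `mask`, `fill` elsewhere (default NA, i.e. outside the analysis mask).
#'
#' @param grid a [brain_grid()].
#' @param mask logical array.
#' @param values numeric vector, one per TRUE voxel of `mask`.
#' @param fill value used outside the mask.
#' @export
volume_from_mask <- function(grid, mask, values, fill = NA_real_) {
  stopifnot(sum(mask) == length(values))
  data <- array(fill, dim = grid$shape)
  data[mask] <- values
  brain_volume(grid, data, mask)
}

#' Check that a volume is a binary (0/1) mask volume
#' @keywords internal
assert_binary <- function(vol, what = "mask") {
  v <- vol$data[vol$brain_mask]
  if (!all(v %in% c(0, 1)))
    stop(sprintf("%s must be binary (0/1); found other values", what))
  invisible(TRUE)
}
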