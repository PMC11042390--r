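#' Brain sampling grid
#'
#' A `brain_grid` ties a voxel lattice to world (scanner/MNI-style)
#' millimetre space through a 4x4 affine. Voxel indices are 0-based and the
#' affine is authoritative: no implicit axis flipping is performed anywhere.
#'
#' @param shape integer triple, voxels per axis.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#' @return An object of class `brain_grid` with fields `shape`, `affine`, and
#'   `voxel_size_mm` (column norms of the linear part).
#' @examples
#' g <- brain_grid(c(16, 16, 16), diag(c(2, 2, 2, 1)))
#' g$voxel_size_mm
#' @export
brain_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (!all(is.finite(affine))) stop("affine contains non-finite values")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps * 100)
    stop("affine is not invertible")
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vox <= 0)) stop("degenerate voxel size")
  structure(list(shape = shape, affine = affine, voxel_size_mm = vox),
            class = "brain_grid")
}

#' @export
print.brain_grid <- function(x, ...) {
  cat("brain_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      "mm\n")
  invisible(x)
}

#' Test two grids for equality
#'
#' Grids are equal iff shapes match and affines agree within `tol` (absolute).
#'
#' @param a,b `brain_grid` objects.
#' @param tol absolute tolerance on affine entries.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b))
    stop(sprintf("grid mismatch between %s: resample upstream, no implicit resampling is done", what))
  invisible(TRUE)
}

#' World-to-voxel and voxel-to-world coordinate transforms
#'
#' Continuous coordinate transforms through the grid affine. Voxel
#' coordinates are 0-based; `world_to_voxel` inverts the affine so
#' `voxel_to_world(grid, world_to_voxel(grid, x)) == x` to numerical
#' precision.
#'
#' @param grid a `brain_grid`.
#' @param xyz_mm numeric triple (or n x 3 matrix) of world coordinates in mm.
#' @param ijk numeric triple (or n x 3 matrix) of 0-based voxel coordinates.
#' @return Coordinates with the same shape as the input.
#' @export
world_to_voxel <- function(grid, xyz_mm) {
  pts <- coord_matrix(xyz_mm)
  inv <- solve(grid$affine)
  out <- cbind(pts, 1) %*% t(inv)
  restore_coords(out[, 1:3, drop = FALSE], xyz_mm)
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(grid, ijk) {
  pts <- coord_matrix(ijk)
  out <- cbind(pts, 1) %*% t(grid$affine)
  restore_coords(out[, 1:3, drop = FALSE], ijk)
}

coord_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    x
  } else {
    stopifnot(length(x) == 3L)
    matrix(as.numeric(x), 1L, 3L)
  }
}

restore_coords <- function(m, template) {
  if (is.matrix(template)) m else drop(m)
}

#' Nearest voxel index for a world coordinate
#'
#' @inheritParams world_to_voxel
#' @return Integer triple of 0-based voxel indices (rounded to nearest).
#' @export
nearest_voxel <- function(grid, xyz_mm) {
  v <- round(world_to_voxel(grid, xyz_mm))
  if (any(v < 0) || any(v > grid$shape - 1L))
    stop("coordinate maps outside the grid")
  as.integer(v)
}

# world coordinates of every voxel in `idx` (1-based linear indices)
voxel_world_coords <- function(grid, idx) {
  ijk <- arrayInd(idx, grid$shape) - 1L
  voxel_to_world(grid, ijk)
}
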