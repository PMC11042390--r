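#' Stimulation-site models
#'
#' A `stimulation_site` is the voxel-weight representation of one causal
#' perturbation: a binary lesion mask, a decaying-sphere TMS site, or a
#' bilateral DBS field pair. Weights lie in [0, 1].
#'
#' @name stimulation_site
NULL

new_stimulation_site <- function(kind, weights, weights_right = NULL,
                                 size_voxels = NA_integer_) {
  w <- weights$data[weights$brain_mask]
  if (any(w < 0 | w > 1)) stop("site weights must lie in [0, 1]")
  npos <- sum(w > 0)
  if (!is.null(weights_right)) npos <- npos +
    sum(weights_right$data[weights_right$brain_mask] > 0)
  if (npos == 0L) stop("site has no positive-weight voxel")
  structure(list(kind = kind, weights = weights,
                 weights_right = weights_right,
                 size_voxels = as.integer(size_voxels)),
            class = "stimulation_site")
}

#' @export
print.stimulation_site <- function(x, ...) {
  cat("stimulation_site:", x$kind, "|",
      sum(x$weights$data[x$weights$brain_mask] > 0), "weighted voxels\n")
  invisible(x)
}

#' TMS site as a decaying sphere
#'
#' Models a TMS stimulation site as a sphere of weights decaying linearly
#' from 1 at the centre to 0 at `max_radius_mm` (default 12 mm), the
#' conventional compact-support profile for scalp-coil stimulation. The
#' decay law is the simplest monotone choice; swap this function for any
#' alternative profile without touching the rest of the pipeline.
#'
#' @param grid a [brain_grid()].
#' @param center_mm world coordinate (mm) of the stimulation centre; must
#'   map inside the grid.
#' @param max_radius_mm radius (mm) at which the weight reaches 0.
#' @return A `stimulation_site` of kind "tms". Weight at voxel v is
#'   `max(0, 1 - d(v, center)/max_radius_mm)` with d the Euclidean world
#'   distance.
#' @export
tms_site <- function(grid, center_mm, max_radius_mm = 12) {
  stopifnot(max_radius_mm > 0)
  vox <- world_to_voxel(grid, center_mm)
  if (any(vox < -0.5) || any(vox > grid$shape - 0.5))
    stop("TMS centre maps outside the grid")
  idx <- seq_len(prod(grid$shape))
  xyz <- voxel_world_coords(grid, idx)
  d <- sqrt(rowSums((xyz - matrix(center_mm, nrow(xyz), 3, byrow = TRUE))^2))
  w <- pmax(0, 1 - d / max_radius_mm)
  vol <- brain_volume(grid, array(w, dim = grid$shape))
  new_stimulation_site("tms", vol,
                       size_voxels = sum(w > 0))
}

#' Lesion site from a binary mask
#'
#' @param mask a binary (0/1) [brain_volume()].
#' @return A `stimulation_site` of kind "lesion"; `size_voxels` is the
#'   lesion volume in voxels, recorded because lesion size enters lesion
#'   analyses as a covariate.
#' @export
lesion_site <- function(mask) {
  stopifnot(inherits(mask, "brain_volume"))
  assert_binary(mask, "lesion mask")
  n <- sum(mask$data[mask$brain_mask] == 1)
  if (n == 0L) stop("lesion mask is empty")
  new_stimulation_site("lesion", mask, size_voxels = n)
}

#' Bilateral DBS field pair
#'
#' DBS patients carry two stimulation fields (left and right electrodes).
#' The hemifields are kept separate and never merged into one seed: they are
#' consumed only by overlap scoring, where each contributes the mean circuit
#' value under its field. One hemifield may be empty (unilateral case); it
#' then contributes 0 downstream.
#'
#' @param left_field,right_field binary [brain_volume()]s on one grid.
#' @return A `stimulation_site` of kind "dbs_pair" with `weights` (left) and
#'   `weights_right`.
#' @export
dbs_pair_site <- function(left_field, right_field) {
  stop_if_grid_mismatch(left_field$grid, right_field$grid, "DBS hemifields")
  assert_binary(left_field, "left DBS field")
  assert_binary(right_field, "right DBS field")
  nl <- sum(left_field$data[left_field$brain_mask] == 1)
  nr <- sum(right_field$data[right_field$brain_mask] == 1)
  if (nl + nr == 0L) stop("both DBS hemifields are empty")
  structure(list(kind = "dbs_pair", weights = left_field,
                 weights_right = right_field,
                 size_voxels = as.integer(nl + nr)),
            class = "stimulation_site")
}

# weights over the in-mask voxels of `mask_arr` (logical array), normalized
# to sum 1; zero vector allowed only for empty hemifields
site_seed_weights <- function(site, mask_arr) {
  w <- site$weights$data
  w[!site$weights$brain_mask] <- 0
  w <- w[mask_arr]
  s <- sum(w)
  if (s <= 0) stop("site weights lie entirely outside the brain mask")
  w / s
}
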