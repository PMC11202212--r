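#' Anisotropic Euclidean distance to a neuron surface
#'
#' Computes, for every voxel centre, the exact Euclidean distance in
#' micrometres to the nearest mask voxel centre, honouring anisotropic
#' voxel spacing (separable exact squared-distance transform). The
#' distance is zero on every mask voxel, so the interior of the neuron
#' counts as distance zero: a spot that falls inside the traced surface
#' is assigned to the first distance bin.
#'
#' @param mask a nonempty \code{\link{surface_mask}}.
#' @return A \code{"distance_field"}: numeric 3D array of distances (um)
#'   with the mask's spacing attached.
#' @export
distance_to_surface <- function(mask) {
  if (!inherits(mask, "surface_mask")) stop("`mask` must be a surface_mask")
  if (!any(mask)) stop("mask is empty; cannot compute a distance field")
  d <- dim(mask)
  out <- cpp_edt3d(as.logical(mask), d, spacing_um(mask))
  structure(array(out, d), spacing_um = spacing_um(mask),
            class = c("distance_field", "array"))
}

#' @export
print.distance_field <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("distance field: %d x %d x %d voxels, range [0, %.3g] um\n",
              d[1], d[2], d[3], max(x)))
  invisible(x)
}

#' Surface distance at spot positions
#'
#' Evaluates a distance field at arbitrary physical coordinates by
#' trilinear interpolation between the eight surrounding voxel centres
#' (clamped at the stack faces).
#'
#' @param spots a \code{\link{spot_set}} or an \code{n x 3} matrix of
#'   \code{(z, y, x)} coordinates in micrometres.
#' @param field a \code{"distance_field"} from
#'   \code{\link{distance_to_surface}}.
#' @return Numeric vector of distances in micrometres, one per spot.
#' @export
spot_distances <- function(spots, field) {
  coords <- if (inherits(spots, "spot_set"))
    as.matrix(as.data.frame(spots)[, c("z_um", "y_um", "x_um")])
  else as.matrix(spots)
  if (nrow(coords) == 0L) return(numeric(0))
  sp <- spacing_um(field)
  .check_bounds(coords, dim(field), sp, what = "spot")
  interp_trilinear(field, coords)
}

# Trilinear interpolation of a 3D array at physical (z,y,x) coordinates.
# Fractional voxel index u = coord/spacing + 0.5; clamped to [1, n].
interp_trilinear <- function(arr, coords) {
  cpp_interp3d(as.numeric(arr), dim(arr), spacing_um(arr), as.matrix(coords))
}

# internal: look up the voxel a physical point falls in (TRUE if inside mask)
.points_in_mask <- function(mask, coords) {
  d <- dim(mask)
  sp <- spacing_um(mask)
  iz <- pmin(pmax(floor(coords[, 1] / sp[1]) + 1, 1L), d[1])
  iy <- pmin(pmax(floor(coords[, 2] / sp[2]) + 1, 1L), d[2])
  ix <- pmin(pmax(floor(coords[, 3] / sp[3]) + 1, 1L), d[3])
  mask[cbind(iz, iy, ix)]
}

# internal: Gaussian blur of a 3D array with sigma given in um per axis
.blur_um <- function(arr, spacing, sigma_um) {
  sig_vox <- sigma_um / spacing
  out <- cpp_gauss_blur3d(as.numeric(arr), dim(arr), sig_vox)
  array(out, dim(arr))
}
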