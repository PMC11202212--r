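#' Acquisition geometry of a confocal z-stack
#'
#' Describes the voxel grid of a 3D acquisition: number of voxels per
#' axis and physical voxel spacing in micrometres. The default spacing
#' matches a typical high-NA confocal protocol for striatal sections
#' (0.2 um z-steps, 0.299 um pixels); the default 60 x 256 x 256 grid
#' is a desk-scale stand-in for a full 55-60 slice field of view.
#'
#' Axis order is \code{(z, y, x)} throughout the package. Voxel \code{i}
#' (1-based) along an axis with spacing \code{s} covers the physical
#' interval \code{[(i-1)*s, i*s)} and has its centre at \code{(i-0.5)*s},
#' so the stack occupies \code{[0, n*s)} per axis.
#'
#' @param shape integer vector \code{(nz, ny, nx)}, each at least 8.
#' @param spacing_um numeric vector \code{(dz, dy, dx)} of positive
#'   voxel spacings in micrometres.
#' @return An object of class \code{"acq_geometry"}.
#' @examples
#' acq_geometry(c(20, 64, 64))
#' @export
acq_geometry <- function(shape = c(60L, 256L, 256L),
                         spacing_um = c(0.2, 0.299, 0.299)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 8L))
    stop("`shape` must be three integers (nz, ny, nx), each >= 8")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) ||
      any(spacing_um <= 0))
    stop("`spacing_um` must be three positive spacings (dz, dy, dx)")
  structure(list(shape = shape, spacing_um = spacing_um),
            class = "acq_geometry")
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf("acquisition geometry: %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  invisible(x)
}

#' Physical extent of a geometry, stack or mask
#'
#' @param x an \code{acq_geometry}, \code{channel_stack} or
#'   \code{surface_mask}.
#' @return numeric \code{(z, y, x)} extent in micrometres.
#' @export
extent_um <- function(x) {
  if (inherits(x, "acq_geometry")) return(x$shape * x$spacing_um)
  dim(x) * spacing_um(x)
}

#' Single-channel 3D image stack
#'
#' A \code{channel_stack} is a numeric 3D array in \code{(z, y, x)}
#' order carrying its voxel spacing in micrometres, the unit every
#' analysis stage consumes and produces.
#'
#' @param data numeric 3D array \code{[z, y, x]}.
#' @param spacing_um voxel spacing \code{(dz, dy, dx)} in micrometres.
#' @return An object of class \code{"channel_stack"}.
#' @export
channel_stack <- function(data, spacing_um) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array [z, y, x]")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(spacing_um <= 0))
    stop("`spacing_um` must be three positive values")
  structure(data, spacing_um = spacing_um,
            class = c("channel_stack", "array"))
}

#' Voxel spacing of a stack, mask or distance field
#' @param x object carrying a \code{spacing_um} attribute.
#' @return numeric \code{(dz, dy, dx)} in micrometres.
#' @export
spacing_um <- function(x) {
  s <- attr(x, "spacing_um")
  if (is.null(s)) stop("object carries no `spacing_um` attribute")
  s
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x); s <- spacing_um(x)
  cat(sprintf("channel stack: %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], s[1], s[2], s[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Binary segmented volume with its boundary surface
#'
#' Wraps a logical voxel mask (a traced neuron, or a binarized fiber
#' channel) together with voxel spacing. The surface is the set of mask
#' voxels with at least one of their six face neighbours outside the
#' mask (voxels on the stack border count as surface).
#'
#' @param voxels logical 3D array \code{[z, y, x]}.
#' @param spacing_um voxel spacing \code{(dz, dy, dx)} in micrometres.
#' @param smoothing_detail_um surface smoothing scale recorded with the
#'   mask (default 0.145 um).
#' @return An object of class \code{"surface_mask"}.
#' @export
surface_mask <- function(voxels, spacing_um, smoothing_detail_um = 0.145) {
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array")
  v <- array(as.logical(voxels), dim = dim(voxels))
  structure(v, spacing_um = as.numeric(spacing_um),
            smoothing_detail_um = smoothing_detail_um,
            class = c("surface_mask", "array"))
}

#' @export
print.surface_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("surface mask: %d x %d x %d voxels, %d foreground (%.3g um^3)\n",
              d[1], d[2], d[3], sum(x), mask_volume_um3(x)))
  invisible(x)
}

#' Total mask volume in cubic micrometres
#' @param mask a \code{surface_mask}.
#' @return numeric scalar, voxel count times voxel volume.
#' @export
mask_volume_um3 <- function(mask) {
  sum(mask) * prod(spacing_um(mask))
}

#' Boundary voxels of a mask
#'
#' @param mask a \code{surface_mask}.
#' @return integer matrix with one row per surface voxel and columns
#'   \code{(z, y, x)} of 1-based voxel indices.
#' @export
surface_voxels <- function(mask) {
  d <- dim(mask)
  m <- array(FALSE, d + 2L)               # FALSE padding: border is surface
  m[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  inner <- m[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  core <- inner &
    m[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    m[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    m[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
    m[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
    m[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
    m[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  which(inner & !core, arr.ind = TRUE, useNames = FALSE)
}

#' Point spots with physical coordinates
#'
#' Detected or simulated point objects. Coordinates are micrometres in
#' the stack frame (see \code{\link{acq_geometry}} for the voxel-centre
#' convention).
#'
#' @param coords_um numeric matrix or data frame with columns
#'   \code{z_um, y_um, x_um}.
#' @param diameter_um nominal spot diameter (default 0.723 um, the
#'   smallest axon calibre the detector is tuned to).
#' @param quality optional per-spot detection score.
#' @return A data frame of class \code{"spot_set"} with columns
#'   \code{z_um, y_um, x_um, quality} and a \code{diameter_um}
#'   attribute.
#' @export
spot_set <- function(coords_um, diameter_um = 0.723, quality = NULL) {
  coords_um <- as.data.frame(coords_um)
  if (!all(c("z_um", "y_um", "x_um") %in% names(coords_um))) {
    if (ncol(coords_um) >= 3L) names(coords_um)[1:3] <- c("z_um", "y_um", "x_um")
    else stop("`coords_um` needs columns z_um, y_um, x_um")
  }
  if (diameter_um <= 0) stop("`diameter_um` must be positive")
  df <- coords_um[, c("z_um", "y_um", "x_um")]
  df$quality <- if (is.null(quality)) rep(NA_real_, nrow(df)) else as.numeric(quality)
  structure(df, diameter_um = diameter_um,
            class = c("spot_set", "data.frame"))
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot set: %d spots, diameter %.3g um\n",
              nrow(x), attr(x, "diameter_um")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more\n", nrow(x) - 5L))
  invisible(x)
}

# internal: coords matrix (n x 3) in um -> fractional 1-based voxel index
.coord_to_index <- function(coords, spacing) {
  sweep(coords, 2L, spacing, "/") + 0.5
}

# internal: check points lie inside [0, extent) per axis
.check_bounds <- function(coords, dims, spacing, what = "spot") {
  ext <- dims * spacing
  bad <- which(coords[, 1] < 0 | coords[, 1] > ext[1] |
               coords[, 2] < 0 | coords[, 2] > ext[2] |
               coords[, 3] < 0 | coords[, 3] > ext[3])
  if (length(bad))
    stop(sprintf("%s %d lies outside the stack bounds", what, bad[1]))
  invisible(TRUE)
}

# internal: same grid check
.check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      max(abs(spacing_um(a) - spacing_um(b))) > 1e-9)
    stop("masks/stacks are not on the same voxel grid")
  invisible(TRUE)
}
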