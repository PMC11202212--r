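#' Chemoattraction kernel for synthetic spot placement
#'
#' Placement density multiplier as a function of the distance \code{d}
#' (um) to the neuron surface:
#' \deqn{m(d) = 1 + A \cdot 1[d \le R]}{m(d) = 1 + A*[d <= R]} (flat) or
#' \deqn{m(d) = 1 + A \cdot \max(0, 1 - d/R)}{m(d) = 1 + A*max(0, 1 - d/R)}
#' (linear ramp). With \code{amplitude = 0} or \code{radius_um = 0} the
#' kernel is identically 1 and placement is completely spatially random.
#'
#' @param radius_um chemoattraction radius R (um), non-negative.
#' @param amplitude enrichment amplitude A, non-negative.
#' @param profile \code{"flat"} or \code{"linear_ramp"}.
#' @return An object of class \code{"chemo_kernel"}.
#' @examples
#' k <- chemo_kernel(7, 1)
#' kernel_multiplier(k, c(0, 5, 7, 7.01))
#' @export
chemo_kernel <- function(radius_um = 7, amplitude = 1,
                         profile = c("flat", "linear_ramp")) {
  profile <- match.arg(profile)
  if (radius_um < 0 || amplitude < 0)
    stop("`radius_um` and `amplitude` must be non-negative")
  structure(list(radius_um = radius_um, amplitude = amplitude,
                 profile = profile),
            class = "chemo_kernel")
}

#' @rdname chemo_kernel
#' @param kernel a \code{chemo_kernel}.
#' @param d distances in micrometres.
#' @export
kernel_multiplier <- function(kernel, d) {
  if (kernel$amplitude == 0 || kernel$radius_um == 0) return(rep(1, length(d)))
  if (kernel$profile == "flat")
    1 + kernel$amplitude * (d <= kernel$radius_um)
  else
    1 + kernel$amplitude * pmax(0, 1 - d / kernel$radius_um)
}

#' Noise model for synthetic stack rendering
#'
#' Smooth additive background, Poisson shot noise and Gaussian read
#' noise, in that order. \code{photon_scale} converts intensity to
#' expected photon counts: the rendered value is
#' \code{rpois(photon_scale * I) / photon_scale}; \code{Inf} disables
#' shot noise. Rendered intensities are clamped at zero after read
#' noise.
#'
#' @param background_level mean background intensity (same unit as the
#'   rendered signal).
#' @param background_smoothness_um correlation scale of the smooth
#'   background field (um).
#' @param photon_scale photons per intensity unit (Poisson); \code{Inf}
#'   for noiseless.
#' @param read_sigma Gaussian read-noise standard deviation.
#' @return An object of class \code{"noise_model"}.
#' @export
noise_model <- function(background_level = 0, background_smoothness_um = 5,
                        photon_scale = Inf, read_sigma = 0) {
  if (background_level < 0 || read_sigma < 0 || photon_scale <= 0 ||
      background_smoothness_um <= 0)
    stop("invalid noise model parameters")
  structure(list(background_level = background_level,
                 background_smoothness_um = background_smoothness_um,
                 photon_scale = photon_scale,
                 read_sigma = read_sigma),
            class = "noise_model")
}

#' Generate a synthetic neuron mask (soma plus branches)
#'
#' Builds a ground-truth neuron for validation: a spherical soma at the
#' stack centre and \code{n_branches} tube-shaped neurites grown as
#' jittered random walks from the soma surface, reflected off the stack
#' faces so the whole geometry stays inside the volume. Defaults give a
#' medium-sized striatal interneuron-like cell in the default
#' acquisition geometry.
#'
#' @param geom an \code{\link{acq_geometry}}.
#' @param n_branches number of neurites (0 for a bare soma).
#' @param branch_length_um length of each neurite (um).
#' @param soma_radius_um soma radius (um); must fit inside the stack.
#' @param tube_radius_um neurite tube radius (um); at least one voxel of
#'   the finest axis.
#' @param intensity nominal fluorescence intensity of the neuron.
#' @param seed integer seed; identical seeds give identical masks.
#' @return A list with elements \code{mask} (a
#'   \code{\link{surface_mask}}) and \code{model} (soma centre/radius,
#'   branch polylines, intensity).
#' @examples
#' g <- acq_geometry(c(24, 48, 48), c(0.5, 0.5, 0.5))
#' nm <- generate_neuron_mask(g, n_branches = 2, branch_length_um = 8,
#'                            soma_radius_um = 3, seed = 1)
#' sum(nm$mask)
#' @export
generate_neuron_mask <- function(geom, n_branches = 4, branch_length_um = 25,
                                 soma_radius_um = 5, tube_radius_um = 0.75,
                                 intensity = 10, seed = 1) {
  ext <- extent_um(geom)
  sp <- geom$spacing_um
  if (tube_radius_um < min(sp))
    stop("`tube_radius_um` must be at least one voxel of the finest axis")
  centre <- ext / 2
  if (any(soma_radius_um >= ext / 2))
    stop("soma does not fit inside the stack bounds")
  margin <- tube_radius_um + min(sp)
  set.seed(seed)

  branches <- list()
  if (n_branches > 0) {
    step <- 1.0  # um per growth step
    for (b in seq_len(n_branches)) {
      # launch direction: mostly in-plane because sections are thin
      phi <- stats::runif(1, 0, 2 * pi)
      dirv <- c(stats::rnorm(1, 0, 0.15), sin(phi), cos(phi))
      dirv <- dirv / sqrt(sum(dirv^2))
      p <- centre + dirv * soma_radius_um * 0.9
      pts <- matrix(p, ncol = 3)
      n_steps <- max(1L, ceiling(branch_length_um / step))
      for (s in seq_len(n_steps)) {
        dirv <- dirv + c(stats::rnorm(1, 0, 0.05),
                         stats::rnorm(1, 0, 0.25), stats::rnorm(1, 0, 0.25))
        dirv <- dirv / sqrt(sum(dirv^2))
        p_new <- p + dirv * step
        for (a in 1:3) {  # reflect off the stack faces (with margin)
          if (p_new[a] < margin) { p_new[a] <- 2 * margin - p_new[a]; dirv[a] <- -dirv[a] }
          if (p_new[a] > ext[a] - margin) { p_new[a] <- 2 * (ext[a] - margin) - p_new[a]; dirv[a] <- -dirv[a] }
        }
        p <- p_new
        pts <- rbind(pts, p)
      }
      branches[[b]] <- list(points_um = pts, radius_um = tube_radius_um)
    }
  }
  model <- structure(list(soma_center_um = centre,
                          soma_radius_um = soma_radius_um,
                          branches = branches, intensity = intensity),
                     class = "neuron_model")
  mask <- rasterize_neuron(geom, model)
  list(mask = mask, model = model)
}

#' Rasterize a neuron model onto a voxel grid
#'
#' @param geom an \code{\link{acq_geometry}}.
#' @param model a neuron model as returned by
#'   \code{\link{generate_neuron_mask}}.
#' @return A \code{\link{surface_mask}}.
#' @export
rasterize_neuron <- function(geom, model) {
  d <- geom$shape; sp <- geom$spacing_um
  ext <- extent_um(geom)
  if (any(model$soma_center_um - model$soma_radius_um < 0) ||
      any(model$soma_center_um + model$soma_radius_um > ext))
    stop("neuron geometry exceeds the stack bounds")
  vox <- array(FALSE, d)
  zc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3]

  paint_ball <- function(vox, c0, r) {
    iz <- which(abs(zc - c0[1]) <= r)
    iy <- which(abs(yc - c0[2]) <= r)
    ix <- which(abs(xc - c0[3]) <= r)
    if (!length(iz) || !length(iy) || !length(ix)) return(vox)
    dz2 <- (zc[iz] - c0[1])^2
    dy2 <- (yc[iy] - c0[2])^2
    dx2 <- (xc[ix] - c0[3])^2
    sub <- outer(outer(dz2, dy2, "+"), dx2, "+") <= r^2
    vox[iz, iy, ix] <- vox[iz, iy, ix] | sub
    vox
  }
  paint_segment <- function(vox, p0, p1, r) {
    lo <- pmin(p0, p1) - r; hi <- pmax(p0, p1) + r
    iz <- which(zc >= lo[1] & zc <= hi[1])
    iy <- which(yc >= lo[2] & yc <= hi[2])
    ix <- which(xc >= lo[3] & xc <= hi[3])
    if (!length(iz) || !length(iy) || !length(ix)) return(vox)
    grid <- expand.grid(z = zc[iz], y = yc[iy], x = xc[ix])
    v <- p1 - p0
    len2 <- sum(v^2)
    w <- cbind(grid$z - p0[1], grid$y - p0[2], grid$x - p0[3])
    t <- if (len2 > 0) pmin(pmax((w %*% v) / len2, 0), 1) else 0
    dd <- (w[, 1] - t * v[1])^2 + (w[, 2] - t * v[2])^2 + (w[, 3] - t * v[3])^2
    inside <- array(dd <= r^2, c(length(iz), length(iy), length(ix)))
    vox[iz, iy, ix] <- vox[iz, iy, ix] | inside
    vox
  }
  vox <- paint_ball(vox, model$soma_center_um, model$soma_radius_um)
  for (br in model$branches) {
    pts <- br$points_um
    for (i in seq_len(nrow(pts) - 1L))
      vox <- paint_segment(vox, pts[i, ], pts[i + 1L, ], br$radius_um)
  }
  surface_mask(vox, sp)
}

#' Sample ground-truth spots around a neuron
#'
#' Draws spot centres by rejection sampling over the continuous stack
#' volume outside the neuron mask, with acceptance probability
#' \code{m(d)/m(0)} where \code{m} is the chemoattraction kernel and
#' \code{d} the distance to the neuron surface. With a unit kernel this
#' is complete spatial randomness outside the mask.
#'
#' @param mask a nonempty \code{\link{surface_mask}} that does not fill
#'   the stack.
#' @param n_spots number of spots to draw (>= 1).
#' @param kernel a \code{\link{chemo_kernel}}.
#' @param seed integer seed.
#' @param field optional precomputed distance field for \code{mask}.
#' @param diameter_um spot diameter recorded in the returned set.
#' @return A \code{\link{spot_set}} of exact ground-truth coordinates.
#' @export
sample_spots <- function(mask, n_spots, kernel = chemo_kernel(0, 0),
                         seed = 1, field = NULL, diameter_um = 0.723) {
  if (n_spots < 1) stop("`n_spots` must be >= 1")
  if (!any(mask)) stop("mask is empty")
  if (all(mask)) stop("mask fills the stack; acceptance region is empty")
  if (is.null(field)) field <- distance_to_surface(mask)
  ext <- dim(mask) * spacing_um(mask)
  m0 <- kernel_multiplier(kernel, 0)
  set.seed(seed)
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n_spots) {
    n_draw <- max(1000L, ceiling((n_spots - nrow(out)) * 2.5))
    cand <- cbind(stats::runif(n_draw, 0, ext[1]),
                  stats::runif(n_draw, 0, ext[2]),
                  stats::runif(n_draw, 0, ext[3]))
    cand <- cand[!.points_in_mask(mask, cand), , drop = FALSE]
    if (!nrow(cand)) next
    d <- interp_trilinear(field, cand)
    acc <- stats::runif(nrow(cand)) < kernel_multiplier(kernel, d) / m0
    out <- rbind(out, cand[acc, , drop = FALSE])
  }
  out <- out[seq_len(n_spots), , drop = FALSE]
  colnames(out) <- c("z_um", "y_um", "x_um")
  spot_set(out, diameter_um = diameter_um)
}

#' Render a synthetic two-channel stack
#'
#' Channel 1 is the neuron mask at its nominal intensity; channel 2
#' renders every spot as a 3D Gaussian whose full width at half maximum
#' equals the spot diameter. The noise model (background, shot noise,
#' read noise) is applied to both channels.
#'
#' @param geom an \code{\link{acq_geometry}}.
#' @param neuron a neuron model (from \code{\link{generate_neuron_mask}})
#'   or a \code{\link{surface_mask}}; \code{NULL} for an empty channel.
#' @param spots a \code{\link{spot_set}} (may be empty).
#' @param noise a \code{\link{noise_model}}.
#' @param spot_intensity peak intensity of one rendered spot.
#' @param seed integer seed for the noise realization.
#' @return Named list of two \code{\link{channel_stack}}s:
#'   \code{neuron} and \code{spots}.
#' @export
render_stack <- function(geom, neuron = NULL, spots = NULL,
                         noise = noise_model(), spot_intensity = 10,
                         seed = 1) {
  d <- geom$shape; sp <- geom$spacing_um
  ch1 <- array(0, d)
  intensity <- 10
  if (!is.null(neuron)) {
    if (inherits(neuron, "neuron_model")) {
      intensity <- neuron$intensity
      neuron <- rasterize_neuron(geom, neuron)
    }
    ch1 <- array(as.numeric(neuron) * intensity, d)
  }
  ch2 <- array(0, d)
  if (!is.null(spots) && nrow(spots) > 0) {
    coords <- as.matrix(as.data.frame(spots)[, c("z_um", "y_um", "x_um")])
    .check_bounds(coords, d, sp, what = "spot")
    fwhm <- attr(spots, "diameter_um")
    sigma <- rep(fwhm, 3) / (2 * sqrt(2 * log(2)))
    r_vox <- pmax(1L, ceiling(4 * sigma / sp))
    for (i in seq_len(nrow(coords))) {
      u <- coords[i, ] / sp + 0.5                 # fractional voxel index
      i0 <- pmax(1L, floor(u - r_vox)); i1 <- pmin(d, ceiling(u + r_vox))
      gz <- exp(-0.5 * (((i0[1]:i1[1]) - u[1]) * sp[1] / sigma[1])^2)
      gy <- exp(-0.5 * (((i0[2]:i1[2]) - u[2]) * sp[2] / sigma[2])^2)
      gx <- exp(-0.5 * (((i0[3]:i1[3]) - u[3]) * sp[3] / sigma[3])^2)
      ch2[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <-
        ch2[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] +
        spot_intensity * outer(outer(gz, gy), gx)
    }
  }
  # one seed per channel so a change in one channel's noise draw can
  # never shift the other channel's realization
  set.seed(seed)
  ch1 <- apply_noise(ch1, sp, noise)
  set.seed(seed + 1L)
  ch2 <- apply_noise(ch2, sp, noise)
  list(neuron = channel_stack(ch1, sp), spots = channel_stack(ch2, sp))
}

#' Apply a noise model to a clean intensity array
#'
#' @param img numeric 3D array of clean intensities.
#' @param spacing voxel spacing (um), for the background scale.
#' @param noise a \code{\link{noise_model}}.
#' @return Noisy array, same shape, clamped at zero. Uses the current
#'   RNG state; seed upstream for reproducibility.
#' @export
apply_noise <- function(img, spacing, noise) {
  d <- dim(img)
  out <- img
  if (noise$background_level > 0) {
    rough <- array(stats::rnorm(prod(d)), d)
    smooth <- .blur_um(rough, spacing, rep(noise$background_smoothness_um, 3))
    s <- stats::sd(smooth)
    if (s > 0) smooth <- smooth / s
    out <- out + noise$background_level * pmax(0, 1 + 0.25 * smooth)
  }
  if (is.finite(noise$photon_scale))
    out <- array(stats::rpois(length(out), pmax(out, 0) * noise$photon_scale) /
                   noise$photon_scale, d)
  if (noise$read_sigma > 0)
    out <- out + array(stats::rnorm(length(out), 0, noise$read_sigma), d)
  array(pmax(out, 0), d)
}

#' Generate a two-channel pair with known volume-overlap fractions
#'
#' Constructs two binary channel masks A and B whose directional
#' voxel-overlap fractions (A-in-B and B-in-A) hit the requested values
#' to within one voxel of rounding. The masks are contiguous
#' raster-order blocks inside a centred sub-box, so their voxel counts
#' are exact by construction. Requested fraction pairs must be jointly
#' feasible: exactly one of the two fractions being zero is impossible
#' (a nonempty intersection exists for one channel but not the other).
#'
#' @param geom an \code{\link{acq_geometry}}.
#' @param target_frac_a_in_b fraction of A's volume inside B, in [0, 1].
#' @param target_frac_b_in_a fraction of B's volume inside A, in [0, 1].
#' @param vol_a_voxels size of mask A in voxels (default about 4% of
#'   the stack).
#' @param seed integer seed for the placement offset.
#' @return List with \code{mask_a}, \code{mask_b}
#'   (\code{\link{surface_mask}}s) and \code{truth} (the ground-truth
#'   \code{\link{overlap_fractions}} result).
#' @examples
#' g <- acq_geometry(c(16, 32, 32), c(0.5, 0.5, 0.5))
#' cp <- generate_coloc_pair(g, 0.552, 0.979, seed = 1)
#' cp$truth
#' @export
generate_coloc_pair <- function(geom, target_frac_a_in_b, target_frac_b_in_a,
                                vol_a_voxels = NULL, seed = 1) {
  fa <- target_frac_a_in_b; fb <- target_frac_b_in_a
  if (fa < 0 || fa > 1 || fb < 0 || fb > 1)
    stop("target fractions must lie in [0, 1]")
  if (xor(fa == 0, fb == 0))
    stop("infeasible fraction pair: exactly one directional fraction is zero")
  d <- geom$shape
  n_total <- prod(d)
  if (is.null(vol_a_voxels)) vol_a_voxels <- max(64L, round(0.04 * n_total))
  a <- as.integer(vol_a_voxels)
  i <- as.integer(round(fa * a))
  b <- if (fb > 0) as.integer(round(i / fb)) else a
  if (a + b - i > n_total %/% 2L)
    stop("requested masks do not fit in the stack")
  set.seed(seed)
  offset <- sample.int(n_total %/% 4L, 1L)
  idx_a <- offset + seq_len(a)
  idx_b <- offset + a - i + seq_len(b)
  ma <- array(FALSE, d); ma[idx_a] <- TRUE
  mb <- array(FALSE, d); mb[idx_b] <- TRUE
  mask_a <- surface_mask(ma, geom$spacing_um)
  mask_b <- surface_mask(mb, geom$spacing_um)
  list(mask_a = mask_a, mask_b = mask_b,
       truth = overlap_fractions(mask_a, mask_b))
}
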