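#' Segment the neuron surface from an intensity channel
#'
#' Automated counterpart of tracing a neuron by absolute intensity
#' threshold: the channel is lightly smoothed at the surface-detail
#' scale, thresholded, components smaller than
#' \code{min_component_voxels} are dropped, and the largest remaining
#' 26-connected component becomes the mask.
#'
#' @param channel a \code{\link{channel_stack}} (background-subtracted).
#' @param threshold absolute intensity threshold.
#' @param min_component_voxels components below this voxel count are
#'   removed before picking the largest (default 0).
#' @param smoothing_detail_um smoothing scale (um), default 0.145.
#' @return A \code{\link{surface_mask}}.
#' @export
segment_surface <- function(channel, threshold, min_component_voxels = 0L,
                            smoothing_detail_um = 0.145) {
  sp <- spacing_um(channel)
  img <- .blur_um(array(as.numeric(channel), dim(channel)), sp,
                  rep(smoothing_detail_um, 3))
  bin <- img >= threshold
  if (!any(bin))
    stop(sprintf("segmentation produced an empty mask (0 of %d voxels >= %.4g)",
                 length(bin), threshold))
  lab <- cpp_label3d(bin, dim(channel), 26L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= max(min_component_voxels, 1L))
  if (!length(keep))
    stop(sprintf("segmentation empty after removing components < %d voxels (largest was %d)",
                 min_component_voxels, max(sizes)))
  largest <- keep[which.max(sizes[keep])]
  surface_mask(array(lab == largest, dim(channel)), sp,
               smoothing_detail_um = smoothing_detail_um)
}

#' Binarize a fiber channel into a volume mask
#'
#' Like \code{\link{segment_surface}} but keeps every suprathreshold
#' voxel: fiber volumes are fragmented, so no connected-component
#' selection is applied. An empty result is allowed (with a warning).
#'
#' @inheritParams segment_surface
#' @return A \code{\link{surface_mask}} (possibly empty).
#' @export
binarize_channel <- function(channel, threshold,
                             smoothing_detail_um = 0.145) {
  sp <- spacing_um(channel)
  img <- .blur_um(array(as.numeric(channel), dim(channel)), sp,
                  rep(smoothing_detail_um, 3))
  bin <- img >= threshold
  if (!any(bin)) warning("binarized channel is empty")
  surface_mask(array(bin, dim(channel)), sp,
               smoothing_detail_um = smoothing_detail_um)
}

#' Detect point spots in a fiber channel
#'
#' Scale-matched blob detection: the channel is blurred at
#' \code{sigma = diameter_um / (2*sqrt(3))} (the scale at which a
#' Laplacian-of-Gaussian response peaks for a 3D blob of that
#' diameter), the scale-normalized negated Laplacian is computed with
#' anisotropic finite differences, and 26-neighbourhood local maxima
#' with response at or above \code{threshold} become spots. Plateau
#' ties resolve to the lowest (z, y, x) voxel. Centres are refined to
#' sub-voxel precision by the intensity centroid of the blurred channel
#' in a one-diameter window.
#'
#' @param channel a \code{\link{channel_stack}} (background-subtracted).
#' @param diameter_um expected spot diameter (um), at least twice the
#'   finest voxel spacing.
#' @param threshold minimum detection quality (scale-normalized LoG
#'   response, same unit as intensity). Required: appropriate values
#'   depend on the channel's intensity scale.
#' @param refine logical; sub-voxel centroid refinement (default TRUE).
#' @return A \code{\link{spot_set}} with per-spot \code{quality}; empty
#'   when nothing passes the threshold.
#' @export
detect_spots <- function(channel, diameter_um = 0.723, threshold,
                         refine = TRUE) {
  sp <- spacing_um(channel)
  d <- dim(channel)
  if (diameter_um < 2 * min(sp))
    stop("`diameter_um` must be at least twice the finest voxel spacing")
  sigma_um <- diameter_um / (2 * sqrt(3))
  img <- .blur_um(array(as.numeric(channel), d), sp, rep(sigma_um, 3))
  resp <- -sigma_um^2 * .laplacian(img, sp)
  idx <- cpp_local_maxima(as.numeric(resp), d, threshold)
  if (!length(idx)) {
    out <- spot_set(matrix(numeric(0), 0, 3,
                           dimnames = list(NULL, c("z_um", "y_um", "x_um"))),
                    diameter_um = diameter_um)
    return(out)
  }
  ai <- arrayInd(idx, d)
  quality <- resp[idx]
  centers <- sweep(ai - 0.5, 2, sp, "*")
  if (refine) {
    r_vox <- pmax(1L, round(diameter_um / 2 / sp))
    for (k in seq_len(nrow(ai))) {
      i0 <- pmax(1L, ai[k, ] - r_vox); i1 <- pmin(d, ai[k, ] + r_vox)
      w <- img[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
      w <- pmax(w, 0)
      tw <- sum(w)
      if (tw > 0) {
        zc <- (i0[1]:i1[1] - 0.5) * sp[1]
        yc <- (i0[2]:i1[2] - 0.5) * sp[2]
        xc <- (i0[3]:i1[3] - 0.5) * sp[3]
        centers[k, 1] <- sum(apply(w, 1, sum) * zc) / tw
        centers[k, 2] <- sum(apply(w, 2, sum) * yc) / tw
        centers[k, 3] <- sum(apply(w, 3, sum) * xc) / tw
      }
    }
  }
  colnames(centers) <- c("z_um", "y_um", "x_um")
  spot_set(centers, diameter_um = diameter_um, quality = quality)
}

# Discrete Laplacian with physical spacing (replicated boundary).
.laplacian <- function(img, sp) {
  d <- dim(img)
  shift <- function(arr, axis, by) {
    idx <- lapply(d, seq_len)
    i <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
    idx[[axis]] <- i
    arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out <- array(0, d)
  for (a in 1:3)
    out <- out + (shift(img, a, 1L) + shift(img, a, -1L) - 2 * img) / sp[a]^2
  out
}

#' Match detected spots to ground truth
#'
#' Greedy nearest-pair matching: candidate pairs within
#' \code{radius_um} are accepted in order of increasing distance, each
#' spot used at most once. Reports precision, recall and the matched
#' pairs.
#'
#' @param detected,truth \code{\link{spot_set}}s or \code{n x 3}
#'   coordinate matrices (um).
#' @param radius_um maximum match distance.
#' @return List with \code{n_matched}, \code{precision}, \code{recall}
#'   and a two-column matrix \code{pairs} (detected index, truth index).
#' @export
match_spots <- function(detected, truth, radius_um) {
  cm <- function(s) if (inherits(s, "spot_set"))
    as.matrix(as.data.frame(s)[, c("z_um", "y_um", "x_um")]) else as.matrix(s)
  a <- cm(detected); b <- cm(truth)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(list(n_matched = 0L, precision = 0, recall = 0,
                pairs = matrix(integer(0), 0, 2)))
  dd <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  dd[dd < 0] <- 0
  dd <- sqrt(dd)
  cand <- which(dd <= radius_um, arr.ind = TRUE)
  ord <- order(dd[cand])
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  pairs <- matrix(integer(0), 0, 2)
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  list(n_matched = nrow(pairs),
       precision = nrow(pairs) / nrow(a),
       recall = nrow(pairs) / nrow(b),
       pairs = pairs)
}
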