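#' Crop a standardized region of interest from a stack
#'
#' Selects the voxels whose centres fall inside the box
#' \code{[origin, origin + size)} on each axis, preserving spacing
#' metadata. For an axis-aligned ROI this keeps
#' \code{floor(size/spacing + 1/2)} voxels per axis, so the default
#' 185 x 185 x 5 um volumetry ROI at 0.299/0.2 um spacing keeps
#' 619 x 619 x 25 voxels.
#'
#' @param stack a \code{\link{channel_stack}} or
#'   \code{\link{surface_mask}}.
#' @param roi_size_um ROI size \code{(x, y, z)} in micrometres
#'   (default \code{c(185, 185, 5)}).
#' @param origin_um ROI origin \code{(x, y, z)} in micrometres
#'   (default the stack corner).
#' @return The cropped object, same class and spacing.
#' @export
crop_roi <- function(stack, roi_size_um = c(185, 185, 5),
                     origin_um = c(0, 0, 0)) {
  if (any(roi_size_um <= 0)) stop("ROI size must be positive on every axis")
  sp <- spacing_um(stack)
  d <- dim(stack)
  size_zyx <- rev(roi_size_um)    # user-facing (x, y, z) -> internal (z, y, x)
  orig_zyx <- rev(origin_um)
  ext <- d * sp
  if (any(orig_zyx < 0) || any(orig_zyx + size_zyx > ext + 1e-9))
    stop("ROI exceeds the stack bounds")
  first <- floor(orig_zyx / sp + 0.5) + 1L     # first voxel centre inside
  count <- floor((orig_zyx + size_zyx) / sp + 0.5) - first + 1L
  if (any(count < 1L)) stop("ROI is smaller than one voxel on some axis")
  last <- pmin(first + count - 1L, d)
  out <- stack[first[1]:last[1], first[2]:last[2], first[3]:last[3],
               drop = FALSE]
  if (inherits(stack, "surface_mask"))
    surface_mask(out, sp, attr(stack, "smoothing_detail_um"))
  else channel_stack(out, sp)
}

#' Two-marker arborization volume fractions
#'
#' Normalizes the voxel volumes of two marker masks so the two markers
#' sum to 100%: \code{pct_1 = 100 * V1 / (V1 + V2)}. The ratio is
#' always larger over smaller, so it is at least 1.
#'
#' @param mask_1,mask_2 \code{\link{surface_mask}}s on the same ROI
#'   grid (e.g. parvalbumin and DARPP-32 channels), or numeric volumes
#'   in cubic micrometres.
#' @param roi_id identifier.
#' @return A one-row data frame of class \code{"volume_fraction"} with
#'   \code{vol_1_um3, vol_2_um3, pct_1, pct_2, ratio}.
#' @examples
#' channel_volume_fraction(7.61, 92.39)$ratio  # about 12.1
#' @export
channel_volume_fraction <- function(mask_1, mask_2, roi_id = "roi") {
  v1 <- if (is.numeric(mask_1)) mask_1 else mask_volume_um3(mask_1)
  v2 <- if (is.numeric(mask_2)) mask_2 else mask_volume_um3(mask_2)
  if (!is.numeric(mask_1) && !is.numeric(mask_2))
    .check_same_grid(mask_1, mask_2)
  if (v1 + v2 <= 0) stop("both marker volumes are zero")
  p1 <- 100 * v1 / (v1 + v2)
  p2 <- 100 - p1
  res <- data.frame(roi_id = roi_id, vol_1_um3 = v1, vol_2_um3 = v2,
                    pct_1 = p1, pct_2 = p2,
                    ratio = max(p1, p2) / min(p1, p2))
  class(res) <- c("volume_fraction", "data.frame")
  res
}

#' Cohort summary of volume fractions with a group comparison
#'
#' Row-binds per-ROI \code{\link{channel_volume_fraction}} results and
#' compares the two markers' percentages across ROIs with an unpaired
#' two-tailed Student's t-test.
#'
#' @param results list of \code{"volume_fraction"} rows or a data frame.
#' @return List with \code{per_roi} (the bound table), \code{mean_pct_1},
#'   \code{mean_pct_2}, \code{mean_ratio}, and \code{t_test}
#'   (\code{t}, \code{df}, \code{p}).
#' @export
volume_fraction_cohort <- function(results) {
  df <- if (is.data.frame(results)) results else do.call(rbind, results)
  if (nrow(df) < 2L) stop("need at least 2 ROIs")
  tt <- if (stats::var(df$pct_1) + stats::var(df$pct_2) > 0)
    unpaired_t(df$pct_1, df$pct_2)
  else list(t = NA_real_, df = NA_real_, p = NA_real_)
  list(per_roi = df,
       mean_pct_1 = mean(df$pct_1), mean_pct_2 = mean(df$pct_2),
       mean_ratio = mean(df$ratio), t_test = tt)
}
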