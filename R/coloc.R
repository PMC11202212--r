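#' Directional volume-overlap fractions of two channel masks
#'
#' Voxelwise intersection of two binarized channels on the same grid,
#' with volumes in cubic micrometres and both directional fractions:
#' A-in-B (\code{100 * |A&B| / |A|}) and B-in-A. The identity
#' \code{frac_a_in_b * vol_a = frac_b_in_a * vol_b = 100 * vol_int}
#' holds exactly.
#'
#' @param mask_a,mask_b \code{\link{surface_mask}}s on the same grid.
#' @param roi_id,group optional labels carried into aggregation (e.g.
#'   dorsal/ventral).
#' @return A one-row data frame of class \code{"overlap_result"} with
#'   columns \code{roi_id, group, vol_a_um3, vol_b_um3,
#'   vol_intersection_um3, frac_a_in_b_pct, frac_b_in_a_pct}.
#' @export
overlap_fractions <- function(mask_a, mask_b, roi_id = "roi", group = NA) {
  .check_same_grid(mask_a, mask_b)
  vv <- prod(spacing_um(mask_a))
  na <- sum(mask_a); nb <- sum(mask_b)
  ni <- sum(mask_a & mask_b)
  res <- data.frame(roi_id = roi_id, group = group,
                    vol_a_um3 = na * vv, vol_b_um3 = nb * vv,
                    vol_intersection_um3 = ni * vv,
                    frac_a_in_b_pct = if (na > 0) 100 * ni / na else 0,
                    frac_b_in_a_pct = if (nb > 0) 100 * ni / nb else 0,
                    stringsAsFactors = FALSE)
  class(res) <- c("overlap_result", "data.frame")
  res
}

#' Aggregate overlap results across ROIs
#'
#' Pools directional fractions volume-weighted over regions of
#' interest: \code{pooled = 100 * sum(intersection) / sum(A)}, i.e. the
#' overlap percentage of the whole tissue covered by the ROIs, not a
#' mean of per-ROI ratios. Per-ROI mean and SEM are reported alongside
#' for reference, and per-group pooling (e.g. dorsal vs ventral) when
#' requested.
#'
#' @param results list of \code{\link{overlap_fractions}} results or a
#'   data frame row-binding them.
#' @param by_group also pool within each \code{group} label.
#' @return List with \code{pooled} (one-row data frame),
#'   \code{per_group} (data frame or NULL), and \code{per_roi}
#'   (mean/SEM of the per-ROI fractions).
#' @export
aggregate_overlap <- function(results, by_group = FALSE) {
  df <- if (is.data.frame(results)) results else do.call(rbind, results)
  if (nrow(df) < 1L) stop("no overlap results to aggregate")
  pool <- function(d) data.frame(
    n_roi = nrow(d),
    vol_a_um3 = sum(d$vol_a_um3), vol_b_um3 = sum(d$vol_b_um3),
    vol_intersection_um3 = sum(d$vol_intersection_um3),
    frac_a_in_b_pct = 100 * sum(d$vol_intersection_um3) / sum(d$vol_a_um3),
    frac_b_in_a_pct = 100 * sum(d$vol_intersection_um3) / sum(d$vol_b_um3))
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  per_roi <- data.frame(
    mean_frac_a_in_b_pct = mean(df$frac_a_in_b_pct),
    sem_frac_a_in_b_pct = sem(df$frac_a_in_b_pct),
    mean_frac_b_in_a_pct = mean(df$frac_b_in_a_pct),
    sem_frac_b_in_a_pct = sem(df$frac_b_in_a_pct))
  per_group <- NULL
  if (by_group) {
    gs <- split(df, df$group)
    per_group <- do.call(rbind, lapply(names(gs), function(g)
      cbind(group = g, pool(gs[[g]]))))
  }
  list(pooled = pool(df), per_group = per_group, per_roi = per_roi)
}

#' Count double-positive somata
#'
#' A soma from channel A is double-positive when its voxel overlap with
#' the channel-B mask reaches \code{min_overlap_frac} of its own
#' volume; in centroid mode a soma counts when its centroid falls
#' inside the B mask.
#'
#' @param somata list of \code{\link{surface_mask}}s (one per soma) or
#'   an \code{n x 3} matrix of centroid coordinates (um).
#' @param mask_b the second-channel \code{\link{surface_mask}}.
#' @param min_overlap_frac overlap threshold as a fraction of the
#'   soma's own volume (default 0.5); ignored in centroid mode.
#' @return List with \code{n_double}, \code{n_a_only},
#'   \code{pct_double}, \code{pct_a_only}.
#' @export
count_double_positive <- function(somata, mask_b, min_overlap_frac = 0.5) {
  if (is.matrix(somata) || is.data.frame(somata)) {
    coords <- as.matrix(somata)
    if (nrow(coords) == 0L) stop("`somata` is empty")
    dbl <- .points_in_mask(mask_b, coords)
  } else {
    if (!length(somata)) stop("`somata` is empty")
    dbl <- vapply(somata, function(s) {
      .check_same_grid(s, mask_b)
      n <- sum(s)
      n > 0 && sum(s & mask_b) / n >= min_overlap_frac
    }, logical(1))
  }
  n <- length(dbl)
  list(n_double = sum(dbl), n_a_only = n - sum(dbl),
       pct_double = 100 * sum(dbl) / n,
       pct_a_only = 100 * (n - sum(dbl)) / n)
}

#' Reporter recombination rate
#'
#' Percentage of expected reporter-expressing cells actually observed:
#' \code{100 * n_observed_reporter / (expected_pv_frac * n_pv)}, where
#' \code{expected_pv_frac} is the literature fraction of parvalbumin
#' neurons co-expressing the gene of interest (default 0.83).
#'
#' @param n_observed_reporter observed reporter-positive cell count.
#' @param n_pv counted parvalbumin-positive cells (> 0).
#' @param expected_pv_frac expected co-expression fraction in (0, 1].
#' @return Recombination rate as a percentage.
#' @examples
#' recombination_rate(10, 150)  # 8.03
#' @export
recombination_rate <- function(n_observed_reporter, n_pv,
                               expected_pv_frac = 0.83) {
  if (n_pv <= 0) stop("`n_pv` must be positive")
  if (expected_pv_frac <= 0 || expected_pv_frac > 1)
    stop("`expected_pv_frac` must lie in (0, 1]")
  100 * n_observed_reporter / (expected_pv_frac * n_pv)
}
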