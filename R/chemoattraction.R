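#' Standard distance bin edges
#'
#' Coarse bins span 0-30 um in 5 um steps (overview profile); fine bins
#' span 0-15 um in 1 um steps (radius estimation). Bins are half-open
#' \code{[lo, hi)}; spots beyond the last edge are counted but excluded
#' from the binned profile and from testing.
#'
#' @param type \code{"fine"} (default) or \code{"coarse"}.
#' @return Numeric vector of bin edges (um).
#' @export
distance_bins <- function(type = c("fine", "coarse")) {
  type <- match.arg(type)
  if (type == "fine") seq(0, 15, by = 1) else seq(0, 30, by = 5)
}

#' Monte Carlo random-placement null for spot distances
#'
#' Each replicate places \code{n_spots} uniformly at random over the
#' continuous stack volume minus the exclusion mask (the neuron
#' interior), evaluates their surface distances on the distance field,
#' and bins them. This is the complete-spatial-randomness reference the
#' observed profile is normalized against; simulating it in the same
#' bounded volume as the data makes the normalization robust to edge
#' effects.
#'
#' @param n_spots spots per replicate (>= 1).
#' @param field a \code{"distance_field"} for the neuron mask.
#' @param exclusion a \code{\link{surface_mask}} on the same grid whose
#'   interior is excluded from placement, or \code{NULL} to place
#'   anywhere.
#' @param n_sims number of replicates (default 1000).
#' @param bin_edges distance bin edges (um).
#' @param seed integer seed.
#' @return Integer matrix \code{n_sims x n_bins} of per-replicate bin
#'   counts, with attribute \code{n_spots}.
#' @export
simulate_null <- function(n_spots, field, exclusion = NULL, n_sims = 1000L,
                          bin_edges = distance_bins(), seed = 1) {
  if (n_spots < 1) stop("`n_spots` must be >= 1")
  if (!is.null(exclusion)) {
    .check_same_grid(field, exclusion)
    if (all(exclusion)) stop("exclusion mask covers the entire volume")
  }
  ext <- dim(field) * spacing_um(field)
  n_bins <- length(bin_edges) - 1L
  need <- as.integer(n_sims) * as.integer(n_spots)
  set.seed(seed)
  dists <- numeric(0)
  while (length(dists) < need) {
    n_draw <- max(2000L, ceiling((need - length(dists)) * 1.2))
    cand <- cbind(stats::runif(n_draw, 0, ext[1]),
                  stats::runif(n_draw, 0, ext[2]),
                  stats::runif(n_draw, 0, ext[3]))
    if (!is.null(exclusion))
      cand <- cand[!.points_in_mask(exclusion, cand), , drop = FALSE]
    if (!nrow(cand)) next
    dists <- c(dists, interp_trilinear(field, cand))
  }
  dists <- dists[seq_len(need)]
  sim_id <- rep(seq_len(n_sims), each = n_spots)
  bin <- findInterval(dists, bin_edges, rightmost.closed = FALSE)
  ok <- bin >= 1L & bin <= n_bins
  counts <- matrix(tabulate(bin[ok] + n_bins * (sim_id[ok] - 1L),
                            nbins = n_bins * n_sims),
                   nrow = n_sims, ncol = n_bins, byrow = TRUE)
  attr(counts, "n_spots") <- as.integer(n_spots)
  counts
}

#' Distance-binned enrichment profile for one neuron
#'
#' Normalizes observed per-bin spot counts by the mean of the Monte
#' Carlo null ensemble: \code{normalized_pct = 100 * observed /
#' null_mean} per bin. Bins whose null mean is zero are reported as
#' \code{NA} and excluded from downstream tests.
#'
#' @param spot_d numeric vector of observed spot-to-surface distances
#'   (um), e.g. from \code{\link{spot_distances}}.
#' @param null_counts replicate-by-bin matrix from
#'   \code{\link{simulate_null}} generated on the same field and bins.
#' @param bin_edges the bin edges used for the null.
#' @param neuron_id identifier carried through to cohort summaries.
#' @return An object of class \code{"chemo_profile"}: a list with
#'   \code{bin_edges}, per-bin \code{observed}, \code{null_mean},
#'   \code{null_sd}, \code{normalized_pct}, plus \code{n_spots} and
#'   \code{neuron_id}.
#' @export
enrichment_profile <- function(spot_d, null_counts,
                               bin_edges = distance_bins(),
                               neuron_id = "neuron") {
  n_bins <- length(bin_edges) - 1L
  if (ncol(null_counts) != n_bins)
    stop("`null_counts` has a different number of bins than `bin_edges`")
  bin <- findInterval(spot_d, bin_edges, rightmost.closed = FALSE)
  observed <- tabulate(bin[bin >= 1L & bin <= n_bins], nbins = n_bins)
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2, stats::sd)
  pct <- ifelse(null_mean > 0, 100 * observed / null_mean, NA_real_)
  structure(list(bin_edges = bin_edges, observed = observed,
                 null_mean = null_mean, null_sd = null_sd,
                 normalized_pct = pct,
                 n_spots = length(spot_d),
                 n_sims = nrow(null_counts),
                 neuron_id = neuron_id),
            class = "chemo_profile")
}

#' Fit the enrichment profile of one neuron
#'
#' Convenience wrapper running the whole per-neuron statistic: distance
#' field from the mask, observed spot distances, Monte Carlo null
#' (excluding the neuron interior by default, mirroring the generator's
#' physical exclusion), and the normalized profile.
#'
#' @param spots a \code{\link{spot_set}} of observed/detected spots.
#' @param mask the neuron \code{\link{surface_mask}}.
#' @param bin_edges distance bin edges (um).
#' @param n_sims null replicates (default 1000).
#' @param seed integer seed for the null.
#' @param exclude_interior exclude the neuron interior from null
#'   placement (default TRUE).
#' @param field optional precomputed distance field.
#' @param neuron_id identifier for cohort summaries.
#' @return A \code{"chemo_profile"} (see
#'   \code{\link{enrichment_profile}}).
#' @export
chemo_profile <- function(spots, mask, bin_edges = distance_bins(),
                          n_sims = 1000L, seed = 1,
                          exclude_interior = TRUE, field = NULL,
                          neuron_id = "neuron") {
  if (is.null(field)) field <- distance_to_surface(mask)
  d_obs <- spot_distances(spots, field)
  nullm <- simulate_null(length(d_obs), field,
                         exclusion = if (exclude_interior) mask else NULL,
                         n_sims = n_sims, bin_edges = bin_edges, seed = seed)
  enrichment_profile(d_obs, nullm, bin_edges, neuron_id = neuron_id)
}

#' @export
print.chemo_profile <- function(x, ...) {
  cat(sprintf("enrichment profile '%s': %d spots, %d null replicates\n",
              x$neuron_id, x$n_spots, x$n_sims))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.chemo_profile <- function(x, ...) {
  n_bins <- length(x$bin_edges) - 1L
  data.frame(bin_lo_um = x$bin_edges[-(n_bins + 1L)],
             bin_hi_um = x$bin_edges[-1L],
             observed = x$observed,
             null_mean = x$null_mean,
             null_sd = x$null_sd,
             normalized_pct = x$normalized_pct)
}

#' @export
plot.chemo_profile <- function(x, ...) {
  mid <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(mid, x$normalized_pct, type = "b", pch = 16,
                 xlab = "distance from neuron surface (um)",
                 ylab = "spots (% of random placement)", ...)
  graphics::abline(h = 100, lty = 2, col = "grey40")
  invisible(x)
}

#' Fit the cohort-level chemoattraction model
#'
#' Combines per-neuron enrichment profiles into the cohort estimate:
#' per-bin mean and SEM of the normalized percentage, a two-way ANOVA
#' (dataset: observed vs null mean, crossed with distance bin; neurons
#' as replicates) for the overall interaction, Sidak-adjusted per-bin
#' observed-vs-null paired contrasts, and the chemoattraction radius.
#'
#' The radius is the upper edge of the last bin in the maximal
#' contiguous run of bins, starting at distance zero, whose adjusted
#' p-value is below \code{alpha} with observed counts above the null
#' mean; zero when the first bin is not significantly enriched.
#'
#' @param profiles list of \code{"chemo_profile"} objects (>= 2) on
#'   common bins.
#' @param alpha significance level (default 0.05).
#' @return An object of class \code{"chemo_fit"} with elements
#'   \code{bins} (per-bin table: mean, SEM, contrast p, adjusted p),
#'   \code{anova} (two-way ANOVA table), \code{interaction_p},
#'   \code{radius_um}, \code{alpha}, \code{n_neurons}.
#' @export
fit_chemoattraction <- function(profiles, alpha = 0.05) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop("need at least 2 profiles")
  edges <- profiles[[1]]$bin_edges
  for (p in profiles)
    if (!isTRUE(all.equal(p$bin_edges, edges)))
      stop("profiles do not share common bin edges")
  n_bins <- length(edges) - 1L
  n_neu <- length(profiles)

  # per-neuron per-bin percentages of that neuron's own spot total
  obs_pct <- t(vapply(profiles, function(p) 100 * p$observed / p$n_spots,
                      numeric(n_bins)))
  null_pct <- t(vapply(profiles, function(p) 100 * p$null_mean / p$n_spots,
                       numeric(n_bins)))
  norm_pct <- t(vapply(profiles, function(p) p$normalized_pct,
                       numeric(n_bins)))

  long <- data.frame(
    pct = c(as.vector(obs_pct), as.vector(null_pct)),
    dataset = factor(rep(c("observed", "null"), each = n_neu * n_bins)),
    bin = factor(rep(rep(seq_len(n_bins), each = n_neu), 2L)),
    neuron = rep(rep(seq_len(n_neu), n_bins), 2L))
  an <- two_way_anova(pct ~ dataset * bin, data = long)
  interaction_p <- an$p[an$term == "dataset:bin"]

  # per-bin paired contrast (same neuron under observation vs its null)
  diff <- obs_pct - null_pct
  p_raw <- apply(diff, 2, function(dcol) {
    if (stats::sd(dcol) == 0) return(1)
    stats::t.test(dcol)$p.value
  })
  p_adj <- sidak_adjust(p_raw, m = n_bins)
  enriched <- colMeans(diff) > 0
  sig <- !is.na(p_adj) & p_adj < alpha & enriched
  run <- 0L
  while (run < n_bins && sig[run + 1L]) run <- run + 1L
  radius_um <- if (run > 0L) edges[run + 1L] else 0

  bins <- data.frame(
    bin_lo_um = edges[-(n_bins + 1L)], bin_hi_um = edges[-1L],
    mean_pct = colMeans(norm_pct, na.rm = TRUE),
    sem_pct = apply(norm_pct, 2, stats::sd, na.rm = TRUE) / sqrt(n_neu),
    mean_obs_pct = colMeans(obs_pct),
    mean_null_pct = colMeans(null_pct),
    p = p_raw, p_adj = p_adj, significant = sig)
  structure(list(bins = bins, anova = an, interaction_p = interaction_p,
                 radius_um = radius_um, alpha = alpha, n_neurons = n_neu,
                 norm_pct = norm_pct),
            class = "chemo_fit")
}

#' @export
print.chemo_fit <- function(x, ...) {
  cat(sprintf("chemoattraction fit: %d neurons, %d bins\n",
              x$n_neurons, nrow(x$bins)))
  cat(sprintf("  interaction p = %.3g; chemoattraction radius = %g um\n",
              x$interaction_p, x$radius_um))
  invisible(x)
}

#' @export
summary.chemo_fit <- function(object, ...) {
  print(object)
  print(object$bins, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.chemo_fit <- function(object, ...) {
  c(radius_um = object$radius_um)
}

#' @export
plot.chemo_fit <- function(x, ...) {
  b <- x$bins
  mid <- (b$bin_lo_um + b$bin_hi_um) / 2
  graphics::plot(mid, b$mean_pct, type = "b", pch = 16,
                 ylim = range(c(b$mean_pct - b$sem_pct,
                                b$mean_pct + b$sem_pct, 100)),
                 xlab = "distance from neuron surface (um)",
                 ylab = "spots (% of random placement)", ...)
  graphics::arrows(mid, b$mean_pct - b$sem_pct, mid, b$mean_pct + b$sem_pct,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 100, lty = 2, col = "grey40")
  if (x$radius_um > 0) graphics::abline(v = x$radius_um, lty = 3, col = "red")
  invisible(x)
}

#' Compare two chemoattraction cohorts
#'
#' Two-way ANOVA (cohort crossed with distance bin) on the normalized
#' percentages, Sidak-adjusted per-bin unpaired contrasts between the
#' cohorts, and the ratio of the two estimated radii.
#'
#' @param fit_a,fit_b \code{"chemo_fit"} objects on common bins.
#' @param alpha significance level (default 0.05).
#' @return An object of class \code{"chemo_comparison"}: per-bin table
#'   with adjusted p-values, the ANOVA table, and
#'   \code{radius_ratio = radius_a / radius_b}.
#' @export
compare_cohorts <- function(fit_a, fit_b, alpha = 0.05) {
  ba <- fit_a$bins; bb <- fit_b$bins
  if (!isTRUE(all.equal(ba$bin_lo_um, bb$bin_lo_um)))
    stop("cohorts do not share common bins")
  n_bins <- nrow(ba)
  a <- fit_a$norm_pct; b <- fit_b$norm_pct
  long <- data.frame(
    pct = c(as.vector(a), as.vector(b)),
    cohort = factor(c(rep("A", length(a)), rep("B", length(b)))),
    bin = factor(c(rep(seq_len(n_bins), each = nrow(a)),
                   rep(seq_len(n_bins), each = nrow(b)))))
  an <- two_way_anova(pct ~ cohort * bin, data = long)
  p_raw <- vapply(seq_len(n_bins), function(j) {
    va <- a[, j][!is.na(a[, j])]; vb <- b[, j][!is.na(b[, j])]
    if (length(va) < 2L || length(vb) < 2L) return(NA_real_)
    if (stats::sd(va) == 0 && stats::sd(vb) == 0)
      return(if (mean(va) == mean(vb)) 1 else 0)
    stats::t.test(va, vb)$p.value
  }, numeric(1))
  p_adj <- sidak_adjust(p_raw, m = n_bins)
  bins <- data.frame(bin_lo_um = ba$bin_lo_um, bin_hi_um = ba$bin_hi_um,
                     mean_pct_a = colMeans(a, na.rm = TRUE),
                     mean_pct_b = colMeans(b, na.rm = TRUE),
                     p = p_raw, p_adj = p_adj,
                     significant = !is.na(p_adj) & p_adj < alpha)
  ratio <- if (fit_b$radius_um > 0) fit_a$radius_um / fit_b$radius_um else
    if (fit_a$radius_um == 0) 1 else Inf
  structure(list(bins = bins, anova = an,
                 interaction_p = an$p[an$term == "cohort:bin"],
                 radius_a = fit_a$radius_um, radius_b = fit_b$radius_um,
                 radius_ratio = ratio, alpha = alpha),
            class = "chemo_comparison")
}

#' @export
print.chemo_comparison <- function(x, ...) {
  cat(sprintf("cohort comparison: radius A = %g um, radius B = %g um (ratio %.3g)\n",
              x$radius_a, x$radius_b, x$radius_ratio))
  cat(sprintf("  interaction p = %.3g; %d of %d bins differ after Sidak\n",
              x$interaction_p, sum(x$bins$significant), nrow(x$bins)))
  invisible(x)
}
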