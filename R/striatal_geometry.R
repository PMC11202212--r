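#' Literature constants for striatal geometry arithmetic
#'
#' Default constants used by the closed-form geometric estimates:
#' the striatal volume fraction covered by one dopamine axonal arbor
#' (2.7%), the number of striatal neurons inside one arbor volume
#' (75,000), the fraction of striatal neurons expressing GDNF (0.6%),
#' the number of dopamine neurons in one substantia nigra (7,600), the
#' fractions of striatal neurons that are medium spiny neurons (95%)
#' and parvalbumin interneurons (0.7%), the measured two-marker volume
#' percentages (7.61% / 92.39%), and the chemoattraction distance ratio
#' between GDNF neurons and medium spiny neurons (7).
#'
#' Fields ending in \code{_pct} are percentages; all other fractions
#' are proportions in [0, 1]. The arithmetic operations refuse
#' proportion arguments above 1 so a percentage cannot silently be
#' passed where a fraction is expected.
#'
#' @param arbor_fraction,neurons_per_arbor_volume,gdnf_neuron_fraction,n_da_neurons_sn,msn_fraction,pv_fraction,pv_volume_pct,msn_volume_pct,distance_ratio
#'   see description; defaults are the literature values.
#' @return An object of class \code{"geometry_constants"}.
#' @export
geometry_constants <- function(arbor_fraction = 0.027,
                               neurons_per_arbor_volume = 75000,
                               gdnf_neuron_fraction = 0.006,
                               n_da_neurons_sn = 7600,
                               msn_fraction = 0.95,
                               pv_fraction = 0.007,
                               pv_volume_pct = 7.61,
                               msn_volume_pct = 92.39,
                               distance_ratio = 7) {
  x <- list(arbor_fraction = arbor_fraction,
            neurons_per_arbor_volume = neurons_per_arbor_volume,
            gdnf_neuron_fraction = gdnf_neuron_fraction,
            n_da_neurons_sn = n_da_neurons_sn,
            msn_fraction = msn_fraction,
            pv_fraction = pv_fraction,
            pv_volume_pct = pv_volume_pct,
            msn_volume_pct = msn_volume_pct,
            distance_ratio = distance_ratio)
  if (any(unlist(x) <= 0)) stop("all constants must be positive")
  fr <- c(x$arbor_fraction, x$gdnf_neuron_fraction, x$msn_fraction,
          x$pv_fraction)
  if (any(fr > 1)) stop("fraction constants must not exceed 1")
  if (abs(x$pv_volume_pct + x$msn_volume_pct - 100) > 1e-6)
    stop("volume percentages must sum to 100")
  structure(x, class = "geometry_constants")
}

.check_fraction <- function(x, name) {
  if (x < 0 || x > 1)
    stop(sprintf("`%s` must be a fraction in [0, 1]; got %g (a percentage?)",
                 name, x))
  x
}

#' Effective chemoattraction volume percentage
#'
#' Scales a marker's occupied volume percentage by the chemoattraction
#' distance ratio: a cell type that attracts axons k times farther has
#' a k-fold larger effective interaction volume.
#'
#' @param distance_ratio ratio of chemoattraction radii (> 0).
#' @param volume_pct occupied volume percentage in (0, 100].
#' @return Effective volume percentage.
#' @examples
#' effective_volume_pct(7, 7.61)  # 53.27
#' @export
effective_volume_pct <- function(distance_ratio, volume_pct) {
  if (distance_ratio <= 0) stop("`distance_ratio` must be positive")
  if (volume_pct <= 0 || volume_pct > 100)
    stop("`volume_pct` must be a percentage in (0, 100]")
  distance_ratio * volume_pct
}

#' GDNF neurons inside one dopamine arbor volume
#'
#' @param neurons_per_arbor_volume striatal neurons contained in the
#'   volume covered by one dopamine axonal tree.
#' @param gdnf_fraction fraction of striatal neurons expressing GDNF,
#'   in [0, 1].
#' @return Count, rounded to the nearest integer.
#' @examples
#' gdnf_neurons_per_arbor(75000, 0.006)  # 450
#' @export
gdnf_neurons_per_arbor <- function(neurons_per_arbor_volume, gdnf_fraction) {
  if (neurons_per_arbor_volume < 0) stop("count must be non-negative")
  .check_fraction(gdnf_fraction, "gdnf_fraction")
  round(neurons_per_arbor_volume * gdnf_fraction)
}

#' Expected number of dopamine arbors covering a striatal point
#'
#' With each of \code{n_da_neurons} arbors covering \code{arbor_fraction}
#' of the striatum, a given point is covered by
#' \code{n_da_neurons * arbor_fraction} arbors in expectation.
#'
#' @param n_da_neurons dopamine neurons innervating one striatal side.
#' @param arbor_fraction striatal volume fraction of one arbor, in
#'   [0, 1].
#' @return Expected arbor count (not rounded); \code{floor()} of it is
#'   the conservative "over N" reading.
#' @examples
#' overlapping_arbors(7600, 0.027)  # 205.2
#' @export
overlapping_arbors <- function(n_da_neurons, arbor_fraction) {
  if (n_da_neurons < 0) stop("count must be non-negative")
  .check_fraction(arbor_fraction, "arbor_fraction")
  n_da_neurons * arbor_fraction
}

#' Relative abundance of two cell types
#'
#' @param frac_a,frac_b population fractions in [0, 1]; \code{frac_b}
#'   positive.
#' @return \code{frac_a / frac_b}.
#' @examples
#' abundance_ratio(0.95, 0.007)  # about 135.7
#' @export
abundance_ratio <- function(frac_a, frac_b) {
  .check_fraction(frac_a, "frac_a")
  .check_fraction(frac_b, "frac_b")
  if (frac_b == 0) stop("`frac_b` must be positive")
  frac_a / frac_b
}

#' Table of derived striatal geometry quantities
#'
#' Evaluates the four closed-form estimates from a set of constants:
#' the effective chemoattraction volume of the GDNF system, the number
#' of GDNF neurons per dopamine arbor, the expected number of
#' overlapping dopamine arbors, and the MSN/PV abundance ratio, plus
#' the two-marker volume ratio.
#'
#' @param constants a \code{\link{geometry_constants}} object.
#' @return Data frame with columns \code{quantity}, \code{value},
#'   \code{unit}.
#' @export
geometry_table <- function(constants = geometry_constants()) {
  k <- constants
  data.frame(
    quantity = c("effective_volume_pct", "gdnf_neurons_per_arbor",
                 "overlapping_arbors", "msn_pv_abundance_ratio",
                 "msn_pv_volume_ratio"),
    value = c(effective_volume_pct(k$distance_ratio, k$pv_volume_pct),
              gdnf_neurons_per_arbor(k$neurons_per_arbor_volume,
                                     k$gdnf_neuron_fraction),
              overlapping_arbors(k$n_da_neurons_sn, k$arbor_fraction),
              abundance_ratio(k$msn_fraction, k$pv_fraction),
              k$msn_volume_pct / k$pv_volume_pct),
    unit = c("%", "neurons", "arbors", "fold", "fold"))
}
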