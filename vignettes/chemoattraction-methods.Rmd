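---
title: "Quantifying chemoattraction of axonal spots around neuron surfaces"
author: "striatax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chemoattraction of axonal spots around neuron surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatax)
```

## The question and the statistic

In striatal tissue, neurotrophic-factor-secreting interneurons are rare
(under 1% of neurons), yet incoming dopamine axons carrying the matching
receptor may preferentially grow towards them. The measurable trace of
such chemoattraction in a 3D confocal stack is an excess of axonal
signal near the surface of the secreting neuron, relative to what a
spatially random arrangement of the same amount of signal would give.

`striatax` quantifies this as follows. Fibrous axonal signal is reduced
to point **spots** at a fixed detection diameter (default 0.723 µm, the
calibre of the thinnest axons of interest). The neuron of interest is
segmented into a voxel **surface mask**. For each spot, the anisotropic
Euclidean distance to the nearest mask voxel is computed, and spots are
counted in distance bins (fine: 1 µm bins from 0–15 µm; coarse: 5 µm
bins from 0–30 µm; bins are half-open `[lo, hi)`). The observed binned
counts are compared to a Monte Carlo null: the same number of spots
placed uniformly at random in the same imaged volume, excluding the
neuron interior, re-binned; by default 1000 replicates per neuron. The
per-bin **normalized percentage** is

$$\mathrm{pct}_b \;=\; 100 \cdot \frac{\text{observed count in } b}
{\text{mean null count in } b},$$

so 100% means "exactly as expected by chance". Because the null is
simulated inside the same bounded stack, boundary truncation affects
numerator and denominator alike and cancels; a neuron close to the
stack border is normalized correctly without any analytic edge
correction (this is verified by simulation in the test suite).

## Cohort inference and the chemoattraction radius

Each neuron is its own experiment: it is normalized against its own
1000-replicate null, and neurons are the replicates of the cohort.
`fit_chemoattraction()` reports, per bin, the cohort mean ± SEM of the
normalized percentage, a two-way ANOVA (dataset = observed vs null
mean, crossed with distance bin; Type II sums of squares so unbalanced
cohorts are handled), and per-bin observed-vs-null contrasts with Šidák
adjustment, $p_{\mathrm{adj}} = 1 - (1-p)^m$, where the family size
$m$ is the number of bins tested (15 fine or 6 coarse).

The per-bin contrast is a *paired* t-test across neurons of the
observed bin percentage against the same neuron's null-mean bin
percentage. Pairing by neuron removes between-neuron geometric
variation (arbor size, position in the stack), which is nuisance for
the question "is there excess signal near *this* surface?"; under
complete spatial randomness the paired differences have mean zero, so
the test is calibrated, which the test suite checks directly.

The **chemoattraction radius** is the upper edge of the last bin in the
maximal contiguous run of bins that starts at distance zero and in
which the Šidák-adjusted p-value is below α (default 0.05) *with
observed above null*. If the first bin is not significantly enriched
the radius is zero. The directional condition matters: a generator that
concentrates spots near the surface necessarily depletes them farther
away, and the resulting significant *deficits* beyond the radius must
not extend the run.

`compare_cohorts()` applies the same machinery between two cohorts
(e.g. secreting neurons vs medium spiny neurons): two-way ANOVA of
cohort × bin on the normalized percentages, Šidák-adjusted unpaired
per-bin contrasts, and the ratio of the two estimated radii.

## The synthetic-data generator

The study conditions are built into the generator defaults: stacks of
60 × 256 × 256 voxels at (0.2, 0.299, 0.299) µm spacing in (z, y, x) —
a desk-scale version of a 55–60-slice confocal acquisition — cohorts of
40 neurons with 300 spots each, and 1000 null replicates per neuron.

* `generate_neuron_mask()` builds a spherical soma (default radius
  5 µm, a mid-sized interneuron soma) with tube-shaped neurites
  (default 4 branches of 25 µm, radius 0.75 µm) grown as jittered
  random walks, reflected off the stack faces so the geometry stays in
  bounds. Branch launch directions are biased towards the imaging
  plane because physical sections are thin relative to their lateral
  extent.
* `sample_spots()` draws ground-truth spot centres by rejection
  sampling over the continuous stack volume outside the mask with
  acceptance weight $m(d)/m(0)$, where the chemoattraction kernel is
  $m(d) = 1 + A\,[d \le R]$ (flat) or $m(d) = 1 + A\max(0, 1-d/R)$
  (linear ramp). $A = 0$ or $R = 0$ gives complete spatial randomness.
  Rejection sampling is used because the distance field is tabulated,
  not analytic.
* `render_stack()` rasterizes the neuron at its intensity and renders
  each spot as a 3D Gaussian whose FWHM equals the spot diameter, then
  applies smooth background, Poisson shot noise
  (`value = rpois(photon_scale * I) / photon_scale`) and Gaussian read
  noise, clamping at zero. Each channel consumes an independent seed so
  one channel's noise draw can never shift the other's realization.
* `generate_coloc_pair()` constructs two binary channels whose
  directional voxel-overlap fractions hit requested targets exactly
  (contiguous raster-order blocks, so voxel counts are exact by
  construction), with the ground truth returned alongside.

The generator emulates what the statistic consumes, not optics: the
fiber channel is point spots rather than curvilinear fibers (the
analysis reduces fibers to spots anyway), and there is no
depth-dependent attenuation, spectral bleed-through, or multi-neuron
scene. Passing tests therefore demonstrate correctness of the
*statistic and its calibration*, not robustness to every imaging
artifact of real tissue.

## Preprocessing, segmentation, detection

**Background subtraction** (`subtract_background()`) subtracts a
large-scale Gaussian baseline: σ = `filter_width_um / 2` per axis in
physical units, default width 46.2 µm, far above any spot diameter.
The commercial tool this emulates parameterizes its two internal blurs
with additional coefficients whose published description is ambiguous;
the width is the only unambiguous parameter, so the plain
input-minus-blur form is the default and the extra coefficients are
exposed as optional multipliers (`pre_smooth_factor`,
`baseline_factor`) for users who want to mimic that tool. Negatives
are clamped to zero by default; before clamping the operation is
linear.

**Surface segmentation** (`segment_surface()`) replaces interactive
tracing with a reproducible rule: light smoothing at the surface-detail
scale (0.145 µm — the published value is given in nm, which is
sub-atomic and read as a units typo), absolute intensity threshold,
removal of components below a voxel count, and selection of the largest
26-connected component. `binarize_channel()` is the same without
component selection, for fragmented fiber volumes.

**Spot detection** (`detect_spots()`) is scale-matched blob detection:
Gaussian smoothing at σ = diameter/(2√3), the scale at which the
Laplacian-of-Gaussian response of a 3D blob peaks, then the
scale-normalized negated Laplacian with anisotropic finite differences,
26-neighbourhood local maxima above a quality threshold, and sub-voxel
refinement by the intensity centroid in a one-diameter window. The
quality threshold is deliberately a required argument: its scale is the
channel's intensity scale, which only the caller knows. A useful rule
of thumb (used throughout the test suite) is half the LoG response a
noiseless spot of the expected amplitude would give. Plateau ties
resolve to the lowest (z, y, x) voxel so detection is deterministic.

## Numerical choices

* **Distance transform**: exact separable squared-distance transform
  with per-axis physical spacing (no chamfer approximation); distance
  is zero on and *inside* the mask, so a detected spot that falls
  inside the traced surface lands in the first bin. The transform is
  verified against a brute-force minimum over surface voxels to
  10⁻⁶ µm.
* **Null domain**: uniform over the stack volume *excluding* the
  neuron interior (config `null$exclude_interior`), mirroring the
  generator's physical exclusion. Excluding or including the interior
  changes the null mass near zero distance; symmetry between observed
  and null placement is what keeps the calibration exact.
* **Spot distances** are trilinear interpolations of the distance
  field at the spot centre, clamped at the stack faces; voxel centres
  sit at `(i - 0.5) * spacing`.
* **ROI cropping** keeps the voxels whose *centres* fall inside the
  requested box, i.e. `floor(size/spacing + 1/2)` voxels per aligned
  axis. This is the only rule under which both a 1-µm ROI at 0.2 µm
  z-spacing (5 slices) and an 18.5-µm ROI at 0.299 µm pixels
  (62 pixels) come out as expected.
* **Overlap aggregation** pools volume-weighted
  (`sum(∩) / sum(A)`), because the target quantity is the overlap
  percentage of the whole imaged tissue, not the mean of per-ROI
  ratios; per-ROI mean ± SEM is reported alongside.
* **Volumetry** normalizes the two marker volumes to sum to 100%
  exactly, and the reported ratio is larger over smaller.
* **Degenerate inputs** fail loudly: empty masks, rank-deficient
  ANOVA designs, zero pooled variance, infeasible overlap-fraction
  pairs (exactly one directional fraction zero), ROIs outside the
  stack, and unknown configuration keys are all errors, not warnings.

## Geometry arithmetic

`geometry_table()` evaluates the closed-form consequences of the
measured quantities combined with literature constants: the effective
interaction volume of the rare-interneuron system (distance ratio ×
occupied volume percentage), the number of secreting neurons inside
one dopamine arbor volume (75,000 × 0.006), the expected number of
arbors overlapping a striatal point (7,600 × 0.027), and the
MSN-to-interneuron abundance ratio (0.95 / 0.007). Fractions and
percentages are separate types here: an argument above 1 where a
fraction is expected is rejected rather than silently rescaled.

## Problem sizes used for validation

The package validates itself on synthetic cohorts of 40 neurons with
300 spots and 1000 null replicates each (the statistic's intended
operating point), 35-ROI colocalization sets, 19-ROI volumetry
cohorts, and 500-spot detection scenes at peak SNR ≈ 5. These sizes
were chosen to match the scale of a typical confocal study of this
kind while remaining comfortable on a laptop; the acceptance script
(`scripts/acceptance.R`) re-runs all of them end to end.

## Known limitations

* Spots are an idealization of fibrous signal; fiber tortuosity and
  length statistics are not modelled, and no attempt is made to infer
  them.
* The ANOVA treats distance bins as fixed effects with neurons as
  replicates; a repeated-measures or mixed-effects formulation is a
  possible refinement the per-bin paired contrasts already
  approximate.
* Colocalization is binary voxel overlap; intensity-correlation
  measures (Pearson, Manders on gray values) are out of scope.
* The geometry arithmetic propagates no uncertainty, since its
  literature constants come without intervals.
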