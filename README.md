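# striatax

Spatial enrichment of axonal spots around neuron surfaces in 3D
confocal stacks.

## What this package is for

Rare striatal interneurons secreting a neurotrophic factor can
chemoattract incoming dopamine axons that carry its receptor. In a
multi-channel confocal z-stack this shows up as an excess of axonal
signal close to the secreting neuron's surface, over and above what a
random arrangement of the same signal would give. `striatax` implements
the full quantitative pipeline for this question, aimed at
neuroanatomists analyzing knock-in reporter stacks and at
methodologists who want a testable, scriptable replacement for
interactive commercial tools:

* reduce fibrous axonal signal to point **spots** at a fixed detection
  diameter (default 0.723 µm) via Laplacian-of-Gaussian blob detection;
* segment the neuron into a voxel **surface mask** and compute exact
  anisotropic Euclidean distances from every spot to the surface;
* compare distance-binned spot counts against a **Monte Carlo
  random-placement null** (default 1000 replicates per neuron) in the
  same imaged volume, giving per-bin normalized percentages
  `100 * observed / null mean`;
* estimate the **chemoattraction radius**: the largest contiguous
  distance from the surface, starting at 0, over which spots are
  significantly enriched (two-way ANOVA + Šidák-adjusted per-bin
  contrasts, α = 0.05);
* measure **volume-overlap colocalization** between two channels
  (directional fractions A-in-B and B-in-A, pooled volume-weighted
  across ROIs), **two-marker arborization volume fractions**, and the
  closed-form **striatal geometry arithmetic** that combines these
  measurements with literature constants.

A synthetic-imaging module generates stacks with known neuron
geometry, a tunable chemoattraction kernel
(`m(d) = 1 + A·[d ≤ R]`), known channel overlaps and realistic noise,
so every stage is validated against ground truth.

## Worked example

Simulate one interneuron-like cell with spots enriched within 3 µm of
its surface, then fit the enrichment profile of a 12-neuron cohort:

```r
library(striatax)

g <- acq_geometry(c(24, 64, 64), c(0.5, 0.5, 0.5))   # (z,y,x), um
neuron <- generate_neuron_mask(g, n_branches = 3, branch_length_um = 10,
                               soma_radius_um = 3, seed = 1)
neuron$mask
#> surface mask: 24 x 64 x 64 voxels, 1360 foreground (170 um^3)

spots <- sample_spots(neuron$mask, 300,
                      chemo_kernel(radius_um = 3, amplitude = 1), seed = 2)
profile <- chemo_profile(spots, neuron$mask, n_sims = 1000, seed = 3)
as.data.frame(profile)[1:6, ]
#>   bin_lo_um bin_hi_um observed null_mean null_sd normalized_pct
#> 1         0         1       12      6.94    2.63          173.0
#> 2         1         2       15     15.65    3.93           95.9
#> 3         2         3       39     21.71    4.34          179.6
#> 4         3         4       33     26.88    4.94          122.8
#> 5         4         5       20     29.37    5.18           68.1
#> 6         5         6       33     26.58    4.63          124.2
```

One neuron with 300 spots is noisy; the cohort fit pools neurons (each
normalized against its own null) and runs the per-bin tests:

```r
profiles <- lapply(1:12, function(i) {
  nm <- generate_neuron_mask(g, n_branches = 3, branch_length_um = 10,
                             soma_radius_um = 3, seed = i)
  sp <- sample_spots(nm$mask, 300, chemo_kernel(3, 1), seed = 100 + i)
  chemo_profile(sp, nm$mask, n_sims = 1000, seed = 200 + i)
})
fit <- fit_chemoattraction(profiles)
fit
#> chemoattraction fit: 12 neurons, 15 bins
#>   interaction p = 1.96e-40; chemoattraction radius = 3 um
```

The generator placed spots at double density within 3 µm of the
surface; the fitted radius recovers exactly that. `summary(fit)` shows
the per-bin table, `plot(fit)` the mean ± SEM profile against the 100%
chance line, and `compare_cohorts(fit_a, fit_b)` contrasts two cohorts
(e.g. factor-secreting neurons vs medium spiny neurons).

The closed-form geometry table:

```r
geometry_table()
#>                quantity    value    unit
#>    effective_volume_pct  53.2700       %
#>  gdnf_neurons_per_arbor 450.0000 neurons
#>      overlapping_arbors 205.2000  arbors
#>  msn_pv_abundance_ratio 135.7143    fold
#>     msn_pv_volume_ratio  12.1406    fold
```

Reading: scaling the interneurons' 7.61% occupied volume by their
7-fold larger chemoattraction radius gives an effective interaction
volume of about 53%; one dopamine arbor volume contains about 450
secreting interneurons; an average striatal point is covered by about
205 dopamine arbors; medium spiny neurons are about 136× more abundant
than the parvalbumin interneurons yet occupy only about 12× more
volume.

A thin command-line wrapper with subcommands `simulate`,
`chemoattract`, `coloc`, `volumetry` and `geometry` is installed at
`inst/cli/striatax` (config-file driven; see `?pipeline_config`).

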