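Package: striatax
Title: Spatial Enrichment of Axonal Spots Around Neuron Surfaces in 3D
    Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies chemoattraction of axonal fibers towards neuron
    surfaces in multi-channel 3D fluorescence z-stacks. Reduces fiber
    signal to point spots, measures anisotropic Euclidean distances from
    spots to a segmented neuron surface, compares distance-binned spot
    counts against a Monte Carlo random-placement null ensemble, and
    estimates the chemoattraction radius from Sidak-adjusted per-bin
    tests. Also provides channel volume-overlap colocalization,
    two-marker arborization volume fractions, closed-form striatal
    geometry arithmetic, and a synthetic stack generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    car,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
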