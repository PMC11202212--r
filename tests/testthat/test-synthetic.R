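test_that("bare soma rasterizes to approximately the sphere volume", {
  g <- acq_geometry(c(24, 24, 24), c(1, 1, 1))
  nm <- generate_neuron_mask(g, n_branches = 0, soma_radius_um = 2,
                             tube_radius_um = 1, seed = 1)
  v_sphere <- 4 / 3 * pi * 2^3
  expect_lt(abs(sum(nm$mask) - v_sphere) / v_sphere, 0.15)
})

test_that("mask generation is deterministic in the seed", {
  g <- small_geom()
  a <- generate_neuron_mask(g, n_branches = 3, branch_length_um = 8,
                            soma_radius_um = 3, seed = 11)
  b <- generate_neuron_mask(g, n_branches = 3, branch_length_um = 8,
                            soma_radius_um = 3, seed = 11)
  expect_identical(as.logical(a$mask), as.logical(b$mask))
  expect_equal(a$model$branches, b$model$branches)
  c <- generate_neuron_mask(g, n_branches = 3, branch_length_um = 8,
                            soma_radius_um = 3, seed = 12)
  expect_false(identical(as.logical(a$mask), as.logical(c$mask)))
})

test_that("soma plus branches form a single 26-connected component", {
  g <- small_geom()
  for (seed in c(1, 5, 9)) {
    nm <- generate_neuron_mask(g, n_branches = 5, branch_length_um = 8,
                               soma_radius_um = 3, seed = seed)
    expect_equal(igraph_n_components(nm$mask), 1L)
  }
})

test_that("a soma larger than the stack is rejected", {
  g <- acq_geometry(c(16, 16, 16), c(0.5, 0.5, 0.5))
  expect_error(generate_neuron_mask(g, n_branches = 0, soma_radius_um = 10,
                                    tube_radius_um = 1, seed = 1),
               "fit|bounds")
})

test_that("kernel multiplier follows its defining forms", {
  flat <- chemo_kernel(7, 1, "flat")
  expect_equal(kernel_multiplier(flat, c(0, 6.9, 7, 7.1, 20)),
               c(2, 2, 2, 1, 1))
  ramp <- chemo_kernel(10, 2, "linear_ramp")
  expect_equal(kernel_multiplier(ramp, c(0, 5, 10, 15)), c(3, 2, 1, 1))
  expect_equal(kernel_multiplier(chemo_kernel(7, 0), c(0, 3)), c(1, 1))
  expect_equal(kernel_multiplier(chemo_kernel(0, 5), c(0, 3)), c(1, 1))
})

test_that("CSR sampling is uniform: equal-volume slabs have equal density", {
  g <- small_geom(c(24, 64, 64))
  nm <- generate_neuron_mask(g, n_branches = 2, branch_length_um = 6,
                             soma_radius_um = 3, seed = 2)
  f <- distance_to_surface(nm$mask)
  sp <- sample_spots(nm$mask, 50000, chemo_kernel(0, 0), seed = 3, field = f)
  d <- spot_distances(sp, f)
  # two slabs with equal available volume, measured by voxel counting
  out_d <- f[!nm$mask]
  edges <- stats::quantile(out_d, c(0.2, 0.45, 0.7))
  v1 <- sum(out_d >= edges[1] & out_d < edges[2])
  v2 <- sum(out_d >= edges[2] & out_d < edges[3])
  n1 <- sum(d >= edges[1] & d < edges[2])
  n2 <- sum(d >= edges[2] & d < edges[3])
  expect_lt(abs(n1 / v1 - n2 / v2) / (n1 / v1), 0.05)
})

test_that("flat kernel doubles spot density within its radius", {
  g <- acq_geometry()  # full-scale stack so d <= 7 um leaves room outside
  nm <- generate_neuron_mask(g, seed = 4)
  f <- distance_to_surface(nm$mask)
  sp <- sample_spots(nm$mask, 50000, chemo_kernel(7, 1, "flat"), seed = 5,
                     field = f)
  d <- spot_distances(sp, f)
  out_d <- f[!nm$mask]
  v_in <- sum(out_d <= 7)
  v_out <- sum(out_d > 7)
  ratio <- (sum(d <= 7) / v_in) / (sum(d > 7) / v_out)
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
})

test_that("kernel amplitude monotonically increases the near fraction", {
  g <- small_geom(c(24, 64, 64))
  nm <- generate_neuron_mask(g, n_branches = 2, branch_length_um = 6,
                             soma_radius_um = 3, seed = 6)
  f <- distance_to_surface(nm$mask)
  frac <- vapply(c(0, 0.5, 1, 2), function(A) {
    sp <- sample_spots(nm$mask, 4000, chemo_kernel(4, A), seed = 7, field = f)
    mean(spot_distances(sp, f) <= 4)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("single-spot sampling returns one spot strictly outside the mask", {
  g <- small_geom()
  nm <- generate_neuron_mask(g, n_branches = 0, soma_radius_um = 3,
                             tube_radius_um = 1, seed = 1)
  sp <- sample_spots(nm$mask, 1, seed = 8)
  expect_equal(nrow(sp), 1L)
  coords <- as.matrix(as.data.frame(sp)[, c("z_um", "y_um", "x_um")])
  expect_false(striatax:::.points_in_mask(nm$mask, coords))
  expect_error(sample_spots(nm$mask, 0), ">= 1")
})

test_that("sampling with identical seeds is bit-identical", {
  g <- small_geom()
  nm <- generate_neuron_mask(g, seed = 1, n_branches = 2,
                             branch_length_um = 6, soma_radius_um = 3)
  a <- sample_spots(nm$mask, 200, chemo_kernel(3, 1), seed = 42)
  b <- sample_spots(nm$mask, 200, chemo_kernel(3, 1), seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("CSR spot distances match the volume-weighted null distribution", {
  g <- small_geom(c(24, 64, 64), c(0.4, 0.4, 0.4))
  nm <- generate_neuron_mask(g, n_branches = 2, branch_length_um = 6,
                             soma_radius_um = 3, seed = 9)
  f <- distance_to_surface(nm$mask)
  sp <- sample_spots(nm$mask, 100000, seed = 10, field = f)
  d <- spot_distances(sp, f)
  # reference: deterministic 2x-oversampled grid of points outside the mask
  ext <- dim(f) * spacing_um(f)
  gz <- seq(0.25 * 0.4, ext[1] - 0.25 * 0.4, by = 0.2)
  gy <- seq(0.25 * 0.4, ext[2] - 0.25 * 0.4, by = 0.2)
  gx <- seq(0.25 * 0.4, ext[3] - 0.25 * 0.4, by = 0.2)
  pts <- as.matrix(expand.grid(z_um = gz, y_um = gy, x_um = gx))
  inside <- striatax:::.points_in_mask(nm$mask, pts)
  ref <- striatax:::interp_trilinear(f, pts[!inside, ])
  ks <- suppressWarnings(stats::ks.test(d, ref)$statistic)
  expect_lt(unname(ks), 0.01)
})

test_that("rendering honours spots, noise limits and determinism", {
  g <- acq_geometry(c(16, 32, 32), c(0.3, 0.3, 0.3))
  nm <- generate_neuron_mask(g, n_branches = 0, soma_radius_um = 2,
                             tube_radius_um = 0.5, seed = 1)

  empty <- spot_set(matrix(numeric(0), 0, 3,
                           dimnames = list(NULL, c("z_um", "y_um", "x_um"))))
  r0 <- render_stack(g, nm$mask, empty, noise_model(), seed = 1)
  expect_true(all(r0$spots == 0))

  one <- spot_set(matrix(c(2.0, 4.7, 6.1), 1, 3,
                         dimnames = list(NULL, c("z_um", "y_um", "x_um"))))
  r1 <- render_stack(g, NULL, one, noise_model(), seed = 1)
  peak <- which(r1$spots == max(r1$spots), arr.ind = TRUE)[1, ]
  centre_um <- (peak - 0.5) * spacing_um(r1$spots)
  expect_true(all(abs(centre_um - c(2.0, 4.7, 6.1)) <= spacing_um(r1$spots)))

  ra <- render_stack(g, nm$mask, one,
                     noise_model(background_level = 1, photon_scale = 10,
                                 read_sigma = 0.2), seed = 5)
  rb <- render_stack(g, nm$mask, one,
                     noise_model(background_level = 1, photon_scale = 10,
                                 read_sigma = 0.2), seed = 5)
  expect_identical(as.numeric(ra$spots), as.numeric(rb$spots))
  expect_true(all(ra$spots >= 0) && all(ra$neuron >= 0))
})

test_that("the high-photon limit approaches the noiseless render", {
  g <- acq_geometry(c(16, 32, 32), c(0.3, 0.3, 0.3))
  one <- spot_set(matrix(c(2.4, 4.8, 4.8), 1, 3,
                         dimnames = list(NULL, c("z_um", "y_um", "x_um"))))
  clean <- render_stack(g, NULL, one, noise_model(background_level = 1,
                                                  photon_scale = Inf),
                        seed = 3)$spots
  noisy <- render_stack(g, NULL, one, noise_model(background_level = 1,
                                                  photon_scale = 1e6),
                        seed = 3)$spots
  rel <- abs(noisy - clean) / pmax(clean, 1e-6)
  expect_lt(median(rel[clean > 1e-3]), 0.01)
})

test_that("coloc pair generation hits requested fractions", {
  g <- acq_geometry(c(16, 32, 32), c(0.5, 0.5, 0.5))
  same <- generate_coloc_pair(g, 1, 1, seed = 1)
  expect_identical(as.logical(same$mask_a), as.logical(same$mask_b))
  expect_equal(same$truth$frac_a_in_b_pct, 100)

  disj <- generate_coloc_pair(g, 0, 0, seed = 2)
  expect_equal(disj$truth$vol_intersection_um3, 0)

  target_pair <- generate_coloc_pair(g, 0.552, 0.979, seed = 3)
  expect_lt(abs(target_pair$truth$frac_a_in_b_pct - 55.2), 0.5)
  expect_lt(abs(target_pair$truth$frac_b_in_a_pct - 97.9), 0.5)

  expect_error(generate_coloc_pair(g, 0, 0.5, seed = 1), "infeasible")
  expect_error(generate_coloc_pair(g, 0.5, 0, seed = 1), "infeasible")
  expect_error(generate_coloc_pair(g, 1.2, 0.5, seed = 1), "0, 1")
})
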