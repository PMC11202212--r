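test_that("surface segmentation recovers a rendered sphere", {
  g <- acq_geometry(c(24, 48, 48), c(0.5, 0.5, 0.5))
  nm <- generate_neuron_mask(g, n_branches = 0, soma_radius_um = 4,
                             tube_radius_um = 1, intensity = 10, seed = 1)
  stack <- render_stack(g, nm$model, NULL, noise_model(), seed = 1)$neuron
  seg <- segment_surface(stack, threshold = 5)
  inter <- sum(seg & nm$mask)
  union <- sum(seg | nm$mask)
  expect_gte(inter / union, 0.9)
})

test_that("small components are removed, the largest is kept", {
  d <- c(16, 32, 32)
  arr <- array(0, d)
  arr[4:13, 4:13, 4:13] <- 10          # 1000 voxels
  arr[14, 25, 25] <- 10                # 1-voxel speck (grows < 10 after blur)
  x <- channel_stack(arr, c(0.5, 0.5, 0.5))
  seg <- segment_surface(x, threshold = 5, min_component_voxels = 10)
  expect_true(seg[8, 8, 8])
  expect_false(seg[14, 25, 25])
  expect_error(segment_surface(channel_stack(array(0, d), c(0.5, 0.5, 0.5)),
                               threshold = 1), "empty")
})

test_that("raising the threshold never grows masks or spot sets", {
  set.seed(3)
  d <- c(16, 32, 32)
  arr <- array(runif(prod(d)) * 2, d)
  arr[8, 16, 16] <- 30
  x <- channel_stack(arr, c(0.4, 0.4, 0.4))
  vols <- vapply(c(0.5, 1, 2, 5), function(th) sum(binarize_channel(x, th)),
                 numeric(1))
  expect_true(all(diff(vols) <= 0))
  counts <- vapply(c(0.5, 2, 8), function(th)
    nrow(detect_spots(x, diameter_um = 1.2, threshold = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("binarize keeps everything at threshold 0 and nothing above max", {
  d <- c(16, 16, 16)
  arr <- array(runif(prod(d)), d)
  x <- channel_stack(arr, c(0.5, 0.5, 0.5))
  expect_equal(sum(binarize_channel(x, 0)), prod(d))
  expect_warning(empty <- binarize_channel(x, max(arr) + 10), "empty")
  expect_equal(sum(empty), 0)
})

test_that("binarization recovers rendered mask volume within 10%", {
  g <- acq_geometry(c(20, 40, 40), c(0.4, 0.4, 0.4))
  cp <- generate_coloc_pair(g, 0.5, 0.5, seed = 4)
  stack <- channel_stack(array(as.numeric(cp$mask_a) * 10, g$shape),
                         g$spacing_um)
  rec <- binarize_channel(stack, threshold = 5)
  expect_lt(abs(sum(rec) - sum(cp$mask_a)) / sum(cp$mask_a), 0.1)
})

test_that("a single noiseless spot is found within one voxel", {
  g <- acq_geometry(c(20, 40, 40), c(0.2, 0.299, 0.299))
  truth <- matrix(c(2.0, 5.5, 6.2), 1, 3,
                  dimnames = list(NULL, c("z_um", "y_um", "x_um")))
  stack <- render_stack(g, NULL, spot_set(truth), noise_model(),
                        spot_intensity = 10, seed = 1)$spots
  det <- detect_spots(stack, threshold = 1)
  expect_equal(nrow(det), 1L)
  err <- abs(as.numeric(as.data.frame(det)[1, 1:3]) - as.numeric(truth))
  expect_true(all(err < min(spacing_um(stack))))
})

test_that("two spots three diameters apart give two detections", {
  g <- acq_geometry(c(20, 40, 40), c(0.2, 0.299, 0.299))
  truth <- rbind(c(2.0, 5.0, 5.0), c(2.0, 5.0, 5.0 + 3 * 0.723))
  colnames(truth) <- c("z_um", "y_um", "x_um")
  stack <- render_stack(g, NULL, spot_set(truth), noise_model(),
                        spot_intensity = 10, seed = 1)$spots
  det <- detect_spots(stack, threshold = 1)
  expect_equal(nrow(det), 2L)
  m <- match_spots(det, truth, radius_um = 0.723)
  expect_equal(m$n_matched, 2L)
})

test_that("doubling the stated spacing doubles reported coordinates", {
  g <- acq_geometry(c(20, 40, 40), c(0.2, 0.299, 0.299))
  truth <- matrix(c(2.0, 5.5, 6.2), 1, 3,
                  dimnames = list(NULL, c("z_um", "y_um", "x_um")))
  stack <- render_stack(g, NULL, spot_set(truth), noise_model(),
                        spot_intensity = 10, seed = 1)$spots
  doubled <- channel_stack(array(as.numeric(stack), dim(stack)),
                           2 * spacing_um(stack))
  a <- detect_spots(stack, diameter_um = 0.723, threshold = 1)
  b <- detect_spots(doubled, diameter_um = 2 * 0.723, threshold = 0.25)
  expect_equal(as.numeric(as.data.frame(b)[1, 1:3]),
               2 * as.numeric(as.data.frame(a)[1, 1:3]), tolerance = 1e-6)
})

test_that("noisy detection keeps precision and recall high", {
  # moderate-scale version of the fidelity check: 150 spots at peak SNR
  # about 5 (amplitude 5, unit read noise)
  g <- acq_geometry(c(40, 128, 128))
  nm <- generate_neuron_mask(g, n_branches = 0, soma_radius_um = 2,
                             tube_radius_um = 0.75, seed = 5)
  truth <- sample_spots(nm$mask, 150, seed = 6)
  stack <- render_stack(g, NULL, truth,
                        noise_model(background_level = 0.5, photon_scale = 20,
                                    read_sigma = 1),
                        spot_intensity = 5, seed = 7)$spots
  pre <- subtract_background(stack, background_config(20))
  # quality threshold at about half the clean-render LoG response
  det <- detect_spots(pre, threshold = 1.3)
  m <- match_spots(det, truth, radius_um = 0.723)
  expect_gte(m$precision, 0.9)
  expect_gte(m$recall, 0.9)
})
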