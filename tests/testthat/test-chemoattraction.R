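test_that("null replicates conserve their spot count", {
  m <- random_blob_mask(c(16, 24, 24), c(0.5, 0.5, 0.5), seed = 1)
  f <- distance_to_surface(m)
  wide <- c(0, 2, 4, 6, 100)           # covers every possible distance
  nc <- simulate_null(10, f, m, n_sims = 1, bin_edges = wide, seed = 2)
  expect_equal(sum(nc), 10)
  narrow <- c(0, 1, 2)
  nc2 <- simulate_null(10, f, m, n_sims = 5, bin_edges = narrow, seed = 2)
  expect_true(all(rowSums(nc2) <= 10))
  expect_error(simulate_null(10, f, surface_mask(array(TRUE, dim(m)),
                                                 spacing_um(m))),
               "entire volume")
})

test_that("the null is deterministic in the seed", {
  m <- random_blob_mask(seed = 2)
  f <- distance_to_surface(m)
  a <- simulate_null(50, f, m, n_sims = 20, seed = 9)
  b <- simulate_null(50, f, m, n_sims = 20, seed = 9)
  expect_identical(a, b)
})

test_that("null bin means are proportional to slab volumes for a plane", {
  d <- c(16, 40, 40)
  vox <- array(FALSE, d)
  vox[, , 1:2] <- TRUE                 # plane slab at the x = 0 face
  m <- surface_mask(vox, c(1, 1, 1))
  f <- distance_to_surface(m)
  edges <- c(1, 4, 7, 10, 13)          # away from both the face and far edge
  nc <- simulate_null(400, f, m, n_sims = 300, bin_edges = edges, seed = 3)
  means <- colMeans(nc)
  sems <- apply(nc, 2, sd) / sqrt(nrow(nc))
  # equal-width slabs of a plane field have equal volume -> equal means
  for (j in 2:length(means))
    expect_lt(abs(means[j] - means[1]), 2 * (sems[j] + sems[1]) + 1e-9)
})

test_that("a CSR observation is self-consistent with its own null", {
  m <- random_blob_mask(c(20, 40, 40), c(0.4, 0.4, 0.4), seed = 4)
  f <- distance_to_surface(m)
  sp <- sample_spots(m, 300, seed = 5, field = f)
  d_obs <- spot_distances(sp, f)
  nc <- simulate_null(300, f, m, n_sims = 400,
                      bin_edges = distance_bins("coarse"), seed = 6)
  pr <- enrichment_profile(d_obs, nc, distance_bins("coarse"))
  ok <- pr$null_mean > 0
  z <- abs(pr$observed - pr$null_mean)[ok] / pr$null_sd[ok]
  expect_true(all(z <= 3))
})

test_that("normalized percentages are plain count ratios", {
  null_counts <- matrix(10, nrow = 4, ncol = 6)
  d_obs <- rep(0.5, 60)                # everything lands in the first bin
  pr <- enrichment_profile(d_obs, null_counts, bin_edges = 0:6)
  expect_equal(pr$normalized_pct, c(600, 0, 0, 0, 0, 0))
  zero_null <- matrix(0, 2, 6)
  pr2 <- enrichment_profile(d_obs, zero_null, bin_edges = 0:6)
  expect_true(all(is.na(pr2$normalized_pct)))
  expect_error(enrichment_profile(d_obs, null_counts, bin_edges = 0:4),
               "bins")
})

test_that("an enriched generator produces an enriched near-surface profile", {
  g <- small_geom(c(24, 64, 64))
  ps <- lapply(1:8, function(i)
    make_profile(g, R = 3, A = 1, n_spots = 300, n_sims = 150, seed = i,
                 bin_edges = distance_bins("coarse")))
  mean_first_bin <- mean(vapply(ps, function(p) p$normalized_pct[1],
                                numeric(1)))
  expect_gt(mean_first_bin, 110)
})

test_that("cohort fitting recovers a small chemoattraction radius", {
  g <- small_geom(c(24, 64, 64))
  ps <- lapply(1:12, function(i)
    make_profile(g, R = 3, A = 1.5, n_spots = 400, n_sims = 150, seed = i))
  fit <- fit_chemoattraction(ps)
  expect_s3_class(fit, "chemo_fit")
  expect_gte(fit$radius_um, 2)
  expect_lte(fit$radius_um, 4)
  expect_lt(fit$interaction_p, 0.001)
  expect_equal(unname(coef(fit)), fit$radius_um)
  expect_error(fit_chemoattraction(ps[1]), "at least 2")
})

test_that("identical cohorts compare as indistinguishable", {
  g <- small_geom(c(24, 64, 64))
  ps <- lapply(1:6, function(i)
    make_profile(g, R = 3, A = 1, n_spots = 200, n_sims = 100, seed = i))
  fit <- fit_chemoattraction(ps)
  cmp <- compare_cohorts(fit, fit)
  expect_true(all(cmp$bins$p_adj > 0.05))
  expect_equal(cmp$radius_ratio, 1)
})

test_that("a doubled amplitude shows up as stronger near-bin enrichment", {
  g <- small_geom(c(24, 64, 64))
  pa <- lapply(1:10, function(i)
    make_profile(g, R = 3, A = 0.75, n_spots = 400, n_sims = 120, seed = i))
  pb <- lapply(1:10, function(i)
    make_profile(g, R = 3, A = 1.5, n_spots = 400, n_sims = 120,
                 seed = i + 400))
  fa <- fit_chemoattraction(pa)
  fb <- fit_chemoattraction(pb)
  expect_gt(fb$bins$mean_pct[1], fa$bins$mean_pct[1])
  cmp <- compare_cohorts(fb, fa)
  expect_lt(cmp$bins$p_adj[1] / 2, 0.05)  # one-sided reading of bin 1
})

test_that("normalization is robust to a neuron near the stack border", {
  d <- c(20, 40, 40)
  sp <- c(0.5, 0.5, 0.5)
  mk_ball <- function(centre_frac) {
    zc <- (seq_len(d[1]) - 0.5) * sp[1]
    yc <- (seq_len(d[2]) - 0.5) * sp[2]
    xc <- (seq_len(d[3]) - 0.5) * sp[3]
    c0 <- centre_frac * d * sp
    vox <- outer(outer((zc - c0[1])^2, (yc - c0[2])^2, "+"),
                 (xc - c0[3])^2, "+") <= 3^2
    surface_mask(vox, sp)
  }
  for (centre in list(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.2))) {
    m <- mk_ball(centre)
    f <- distance_to_surface(m)
    obs <- simulate_null(300, f, m, n_sims = 150,
                         bin_edges = distance_bins("coarse"), seed = 11)
    nul <- simulate_null(300, f, m, n_sims = 500,
                         bin_edges = distance_bins("coarse"), seed = 12)
    pct <- 100 * colMeans(obs) / colMeans(nul)
    ok <- colMeans(nul) > 5
    expect_true(all(abs(pct[ok] - 100) < 5))
  }
})
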