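mk_mask <- function(d, sp, idx) {
  vox <- array(FALSE, d)
  vox[idx] <- TRUE
  surface_mask(vox, sp)
}

test_that("overlap fractions satisfy the defining identities", {
  d <- c(10, 10, 10); sp <- c(0.5, 0.5, 0.5)
  a <- mk_mask(d, sp, 1:200)
  same <- overlap_fractions(a, a)
  expect_equal(same$frac_a_in_b_pct, 100)
  expect_equal(same$frac_b_in_a_pct, 100)

  b <- mk_mask(d, sp, 301:400)
  disj <- overlap_fractions(a, b)
  expect_equal(disj$frac_a_in_b_pct, 0)
  expect_equal(disj$frac_b_in_a_pct, 0)

  nested <- overlap_fractions(a, mk_mask(d, sp, 1:100))  # B = half of A
  expect_equal(nested$frac_a_in_b_pct, 50)
  expect_equal(nested$frac_b_in_a_pct, 100)

  # identity frac_a_in_b * vol_a = frac_b_in_a * vol_b = 100 * vol_int
  r <- overlap_fractions(a, mk_mask(d, sp, 151:500))
  expect_equal(r$frac_a_in_b_pct * r$vol_a_um3, 100 * r$vol_intersection_um3)
  expect_equal(r$frac_b_in_a_pct * r$vol_b_um3, 100 * r$vol_intersection_um3)
  # intersection is symmetric
  r2 <- overlap_fractions(mk_mask(d, sp, 151:500), a)
  expect_equal(r$vol_intersection_um3, r2$vol_intersection_um3)

  expect_error(overlap_fractions(a, mk_mask(c(8, 8, 8), sp, 1:10)), "grid")
})

test_that("aggregation pools volume-weighted, not as a mean of ratios", {
  d <- c(10, 10, 10); sp <- c(1, 1, 1)
  r1 <- overlap_fractions(mk_mask(d, sp, 1:100), mk_mask(d, sp, 61:160),
                          roi_id = "r1", group = "dorsal")   # 40%
  r2 <- overlap_fractions(mk_mask(d, sp, 1:100), mk_mask(d, sp, 41:140),
                          roi_id = "r2", group = "ventral")  # 60%
  agg <- aggregate_overlap(list(r1, r2), by_group = TRUE)
  expect_equal(agg$pooled$frac_a_in_b_pct, 50)
  expect_equal(agg$per_roi$mean_frac_a_in_b_pct, 50)
  expect_equal(sort(agg$per_group$frac_a_in_b_pct), c(40, 60))
  single <- aggregate_overlap(list(r1))
  expect_equal(single$pooled$frac_a_in_b_pct, r1$frac_a_in_b_pct)
  # pooled fraction lies between the per-ROI extremes
  expect_true(agg$pooled$frac_a_in_b_pct >= 40 &&
              agg$pooled$frac_a_in_b_pct <= 60)
})

test_that("generated ROI cohorts reproduce pooled overlap ground truth", {
  g <- acq_geometry(c(16, 32, 32), c(0.5, 0.5, 0.5))
  rois <- lapply(1:35, function(i)
    generate_coloc_pair(g, 0.552, 0.979, vol_a_voxels = 400 + 13 * i,
                        seed = i))
  agg <- aggregate_overlap(lapply(rois, function(r) r$truth))
  expect_lt(abs(agg$pooled$frac_a_in_b_pct - 55.2), 1)
  expect_lt(abs(agg$pooled$frac_b_in_a_pct - 97.9), 1)
})

test_that("double-positive counting works in mask and centroid mode", {
  d <- c(12, 20, 20); sp <- c(0.5, 0.5, 0.5)
  big <- mk_mask(d, sp, 1:3000)
  somata <- lapply(0:9, function(k) mk_mask(d, sp, 1 + 40 * k + 0:19))
  res <- count_double_positive(somata, big)
  expect_equal(res$pct_double, 100)
  none <- count_double_positive(somata, mk_mask(d, sp, 4001:4005))
  expect_equal(none$pct_double, 0)

  # 49 overlapping + 1 outside
  somata50 <- c(lapply(0:48, function(k) mk_mask(d, sp, 1 + 40 * k + 0:19)),
                list(mk_mask(d, sp, 4500:4519)))
  res50 <- count_double_positive(somata50, big)
  expect_equal(res50$n_double, 49L)
  expect_equal(res50$pct_double, 98)
  expect_equal(res50$pct_a_only, 2)

  # centroid mode
  cents <- rbind(c(1, 1, 1), c(5.9, 9.9, 9.9))
  expect_equal(count_double_positive(cents, big)$n_double,
               sum(striatax:::.points_in_mask(big, cents)))
})

test_that("recombination rate is the observed over expected percentage", {
  expect_equal(recombination_rate(83, 100, 0.83), 100)
  expect_equal(recombination_rate(0, 100, 0.83), 0)
  expect_equal(round(recombination_rate(10, 150, 0.83), 2), 8.03)
  expect_error(recombination_rate(5, 0), "positive")
  expect_error(recombination_rate(5, 10, 1.5), "0, 1")
})
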