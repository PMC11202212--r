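# Independent oracles and small fixture builders used across tests.

# Brute-force anisotropic distance: for every voxel centre, the minimum
# Euclidean distance to any surface voxel centre of the mask (0 inside).
brute_force_edt <- function(mask) {
  d <- dim(mask)
  sp <- spacing_um(mask)
  surf <- surface_voxels(mask)
  pz <- (surf[, 1] - 0.5) * sp[1]
  py <- (surf[, 2] - 0.5) * sp[2]
  px <- (surf[, 3] - 0.5) * sp[3]
  out <- array(0, d)
  idx <- which(!mask, arr.ind = TRUE)
  qz <- (idx[, 1] - 0.5) * sp[1]
  qy <- (idx[, 2] - 0.5) * sp[2]
  qx <- (idx[, 3] - 0.5) * sp[3]
  dd2 <- outer(qz, pz, "-")^2 + outer(qy, py, "-")^2 + outer(qx, px, "-")^2
  out[idx] <- sqrt(apply(dd2, 1, min))
  out
}

# Random blob mask: union of a few random balls, guaranteed nonempty
# and not filling the stack.
random_blob_mask <- function(dims = c(24, 24, 24),
                             spacing = c(0.4, 0.3, 0.3),
                             n_balls = 3, seed = 1) {
  set.seed(seed)
  ext <- dims * spacing
  zc <- (seq_len(dims[1]) - 0.5) * spacing[1]
  yc <- (seq_len(dims[2]) - 0.5) * spacing[2]
  xc <- (seq_len(dims[3]) - 0.5) * spacing[3]
  vox <- array(FALSE, dims)
  for (b in seq_len(n_balls)) {
    c0 <- runif(3, 0.25, 0.75) * ext
    r <- runif(1, 0.08, 0.2) * min(ext)
    dz2 <- (zc - c0[1])^2
    dy2 <- (yc - c0[2])^2
    dx2 <- (xc - c0[3])^2
    vox <- vox | (outer(outer(dz2, dy2, "+"), dx2, "+") <= r^2)
  }
  if (!any(vox)) vox[dims[1] %/% 2, dims[2] %/% 2, dims[3] %/% 2] <- TRUE
  surface_mask(vox, spacing)
}

# Count 26-connected components of a mask through igraph, independent
# of the package's own labeling.
igraph_n_components <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0L)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lut <- seq_len(n)
  names(lut) <- key(idx)
  edges <- integer(0)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[r, ], "+")
    hit <- lut[key(nb)]
    ok <- !is.na(hit)
    edges <- c(edges, rbind(which(ok), hit[ok]))
  }
  g <- igraph::make_graph(edges = as.integer(edges), n = n,
                          directed = FALSE)
  igraph::components(g)$no
}

# Small isotropic geometry used in many unit tests
small_geom <- function(dims = c(24, 48, 48), sp = c(0.5, 0.5, 0.5)) {
  acq_geometry(dims, sp)
}

# One small synthetic neuron + enrichment profile, shared by several
# chemoattraction tests.
make_profile <- function(geom, R, A, n_spots = 300, n_sims = 200, seed = 1,
                         bin_edges = distance_bins()) {
  nm <- generate_neuron_mask(geom, seed = seed)
  f <- distance_to_surface(nm$mask)
  sp <- sample_spots(nm$mask, n_spots, chemo_kernel(R, A),
                     seed = seed + 7001, field = f)
  chemo_profile(sp, nm$mask, bin_edges = bin_edges, n_sims = n_sims,
                seed = seed + 9001, field = f)
}
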