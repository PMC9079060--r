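# Shared fixtures: all tiny, generated in code at test time.

# small phantom: 32^3 grid at 0.4 mm, cavity scaled down to fit
small_phantom_spec <- function(seed = 1L, noise_sd = 40, thickening_mm = 0,
                               grid = 32L) {
  phantom_spec(grid_shape = rep(grid, 3), spacing = 0.4,
               semi_axes = c(4.0, 3.4, 3.6) * grid / 32,
               thickening_mm = thickening_mm,
               bone_shell_mm = if (grid < 24) 0.7 else 1.2,
               noise_sd = noise_sd, seed = seed)
}

# jitter ranges scaled for the small test phantoms
small_jitter <- list(size_range = c(0.9, 1.1), rotation_deg = 10,
                     thickening_fraction = 0.5,
                     thickening_range_mm = c(0.8, 1.4))

# random binary array with fixed RNG
random_mask_array <- function(dims, p = 0.5) {
  array(as.integer(runif(prod(dims)) < p), dims)
}

# brute-force boundary voxels (6-neighbour background adjacency), 0-based
boundary_oracle <- function(m) {
  d <- dim(m)
  out <- NULL
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (m[x, y, z] != 1L) next
    nb <- c(
      if (x > 1) m[x - 1, y, z] else 0L, if (x < d[1]) m[x + 1, y, z] else 0L,
      if (y > 1) m[x, y - 1, z] else 0L, if (y < d[2]) m[x, y + 1, z] else 0L,
      if (z > 1) m[x, y, z - 1] else 0L, if (z < d[3]) m[x, y, z + 1] else 0L)
    if (length(nb) < 6 || any(nb == 0L)) out <- rbind(out, c(x, y, z) - 1L)
  }
  out
}

# all-pairs exact symmetric Hausdorff and pooled percentile on boundary sets
hausdorff_oracle <- function(a, b, spacing) {
  pa <- sweep(boundary_oracle(a), 2, spacing, `*`)
  pb <- sweep(boundary_oracle(b), 2, spacing, `*`)
  dmat <- matrix(0, nrow(pa), nrow(pb))
  for (j in seq_len(nrow(pb)))
    dmat[, j] <- sqrt((pa[, 1] - pb[j, 1])^2 + (pa[, 2] - pb[j, 2])^2 +
                        (pa[, 3] - pb[j, 3])^2)
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  list(pooled = c(dab, dba), exact_hd = max(c(max(dab), max(dba))))
}

# a unit cube mesh (8 vertices, 12 triangles) with outward winding
cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = side
  surface_mesh(v, f)
}

# every edge of a closed mesh must be shared by exactly two faces
edge_use_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

# constant-output network: all weights zero, head bias = logit(p)
constant_net <- function(p, base_channels = 2) {
  net <- build_network(network_spec(base_channels), seed = 1)
  net$params <- lapply(net$params, function(x) x * 0)
  for (nm in grep("\\.g[12]$", names(net$params), value = TRUE))
    net$params[[nm]] <- net$params[[nm]] + 1
  net$params[["out.b"]] <- log(p / (1 - p))
  net
}
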