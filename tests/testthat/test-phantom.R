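test_that("noiseless phantom assigns exact HU levels and truth is air only", {
  spec <- small_phantom_spec(seed = 1, noise_sd = 0)
  ph <- generate_phantom(spec)
  hu <- spec$hu_levels
  inside <- ph$truth$voxels == 1L
  expect_true(all(ph$volume$voxels[inside] == hu$air))
  expect_true(sum(inside) > 0)
  expect_setequal(unique(as.vector(ph$volume$voxels)),
                  c(hu$air, hu$soft_tissue, hu$bone))
})

test_that("truth voxel volume approximates the analytic ellipsoid volume", {
  spec <- phantom_spec(grid_shape = c(64, 64, 64), spacing = 0.4,
                       semi_axes = c(9, 7.5, 8), noise_sd = 0, seed = 2)
  ph <- generate_phantom(spec)
  vox_vol <- sum(ph$truth$voxels) * prod(spec$spacing)
  analytic <- 4 / 3 * pi * prod(spec$semi_axes)
  expect_lt(abs(vox_vol - analytic) / analytic, 0.05)
})

test_that("same spec and seed give bit-identical phantoms", {
  spec <- small_phantom_spec(seed = 7, noise_sd = 40)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$voxels, b$truth$voxels)
})

test_that("truth mask is one 26-connected component", {
  ss <- asNamespace("sinusseg")
  for (seed in 1:3) {
    ph <- generate_phantom(small_phantom_spec(seed = seed,
                                              thickening_mm = (seed - 1)))
    lab <- ss$.cpp_label_components(ph$truth$voxels,
                                    as.integer(dim(ph$truth$voxels)))
    expect_length(lab$sizes, 1L)
  }
})

test_that("mucosal lining is excluded from truth and not air-valued", {
  spec <- small_phantom_spec(seed = 4, noise_sd = 0, thickening_mm = 1.6)
  ph <- generate_phantom(spec)
  hu <- spec$hu_levels
  lining <- ph$volume$voxels == hu$mucosa
  expect_gt(sum(lining), 0)
  expect_true(all(ph$truth$voxels[lining] == 0L))
  thin <- generate_phantom(small_phantom_spec(seed = 4, noise_sd = 0))
  # lining shrinks the air cavity
  expect_lt(sum(ph$truth$voxels), sum(thin$truth$voxels))
  expect_error(generate_phantom(small_phantom_spec(thickening_mm = 50)), "cavity")
})

test_that("threshold_air_mask follows the inclusive window convention", {
  soft <- volume(array(40, c(4, 4, 4)), spacing = 1)
  expect_identical(sum(threshold_air_mask(soft)$voxels), 0L)
  v <- volume(array(c(-200, -199, -1024, -1025, 0, -500, 40, 30),
                    c(2, 2, 2)), spacing = 1)
  m <- threshold_air_mask(v)
  expect_identical(as.vector(m$voxels), c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L))
  expect_error(threshold_air_mask(v, lo = 0, hi = -1), "lo")
})

test_that("air threshold on a noiseless phantom reproduces the truth", {
  spec <- small_phantom_spec(seed = 5, noise_sd = 0)
  ph <- generate_phantom(spec)
  air <- threshold_air_mask(ph$volume)
  # without an ostium the cavity is the only air: exact equality
  expect_identical(air$voxels, ph$truth$voxels)

  # with an ostium the air mask is a strict superset (channel + nasal cavity)
  spec2 <- small_phantom_spec(seed = 5, noise_sd = 0)
  spec2$ostium <- list(radius_mm = 0.8, direction = c(1, 0, 0),
                       nasal_semi_axes_mm = c(1.6, 1.6, 1.6))
  ph2 <- generate_phantom(spec2)
  air2 <- threshold_air_mask(ph2$volume)
  expect_true(all(air2$voxels[ph2$truth$voxels == 1L] == 1L))
  expect_gt(sum(air2$voxels), sum(ph2$truth$voxels))
  # restricted to the cavity's connected component it equals the truth
  ss <- asNamespace("sinusseg")
  lab <- ss$.cpp_label_components(air$voxels, as.integer(dim(air$voxels)))
  expect_identical(array(as.integer(lab$labels == which.max(lab$sizes)),
                         dim(air$voxels)), ph$truth$voxels)
})

test_that("generate_dataset jitters, splits disjointly and reproduces", {
  base <- small_phantom_spec()
  parts <- generate_dataset(20, base, jitter = small_jitter, seed = 9,
                            split = c(train = 0.6, val = 0.15, test = 0.25))
  expect_length(parts$train, 12L)
  expect_length(parts$val, 3L)
  expect_length(parts$test, 5L)
  seeds <- unlist(lapply(c(parts$train, parts$val, parts$test),
                         function(s) s$spec$seed))
  expect_identical(anyDuplicated(seeds), 0L)

  # zero-width jitter: identical geometry, independent noise
  samples <- generate_dataset(3, base,
                              jitter = list(size_range = c(1, 1),
                                            rotation_deg = 0,
                                            thickening_fraction = 0),
                              seed = 3)
  expect_identical(samples[[1]]$truth$voxels, samples[[2]]$truth$voxels)
  expect_false(identical(samples[[1]]$volume$voxels, samples[[2]]$volume$voxels))

  # same seed twice: identical sample lists
  a <- generate_dataset(4, base, jitter = small_jitter, seed = 17)
  b <- generate_dataset(4, base, jitter = small_jitter, seed = 17)
  for (i in seq_along(a))
    expect_identical(a[[i]]$volume$voxels, b[[i]]$volume$voxels)
  expect_error(generate_dataset(0, base), "n must be")
})
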