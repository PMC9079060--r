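test_that("weighted BCE matches hand-evaluated closed forms", {
  # single voxel, y = 1, p = 0.5, w = 1 -> ln 2
  expect_lt(abs(weighted_bce(array(0.5, c(1, 1, 1)),
                             array(1L, c(1, 1, 1)), 1) - log(2)), 1e-9)
  # two voxels y = (1, 0), p = (0.5, 0.5), w = 2 -> (2 ln2 + ln2)/2
  expect_lt(abs(weighted_bce(array(0.5, c(2, 1, 1)),
                             array(c(1L, 0L), c(2, 1, 1)), 2) - 1.5 * log(2)),
            1e-9)
  # perfect prediction ~ 0 after clamping
  y <- array(c(1L, 0L, 1L, 0L), c(4, 1, 1))
  expect_lt(weighted_bce(array(as.double(y), dim(y)), y, 3), 1e-6)
  expect_error(weighted_bce(array(0.5, c(2, 2, 2)), array(0L, c(2, 2, 1))),
               "differ")
  expect_error(weighted_bce(array(0.5, c(1, 1, 1)), array(0L, c(1, 1, 1)),
                            w = -1), ">= 0")
})

test_that("weighted BCE equals a brute-force per-voxel loop", {
  set.seed(99)
  for (i in 1:20) {
    p <- array(runif(4^3, 0.01, 0.99), c(4, 4, 4))
    y <- random_mask_array(c(4, 4, 4))
    w <- sample(c(1, 2.5, 7), 1)
    acc <- 0
    for (j in seq_along(p))
      acc <- acc - (w * y[j] * log(p[j]) + (1 - y[j]) * log(1 - p[j]))
    expect_equal(weighted_bce(p, y, w), acc / length(p))
    if (w == 1) expect_equal(weighted_bce(p, y, 1), acc / length(p),
                             tolerance = 1e-14)
    # permutation invariance over voxels
    perm <- sample(length(p))
    expect_equal(weighted_bce(array(p[perm], dim(p)), array(y[perm], dim(y)), w),
                 weighted_bce(p, y, w))
  }
})

test_that("augmentation applies one transform to both image and mask", {
  ph <- generate_phantom(small_phantom_spec(seed = 6, noise_sd = 20))
  idp <- list(rotation = c(0, 0, 0), scale = 1, elastic = NULL)
  a0 <- augment(ph$volume, ph$truth, params = idp)
  expect_identical(a0$volume$voxels, ph$volume$voxels)
  expect_identical(a0$mask$voxels, ph$truth$voxels)

  a1 <- augment(ph$volume, ph$truth, seed = 12)
  expect_true(all(a1$mask$voxels %in% c(0L, 1L)))
  a2 <- augment(ph$volume, ph$truth, seed = 12)
  expect_identical(a1$volume$voxels, a2$volume$voxels)
  expect_identical(a1$mask$voxels, a2$mask$voxels)
  a3 <- augment(ph$volume, ph$truth, seed = 13)
  expect_false(identical(a1$volume$voxels, a3$volume$voxels))
  # a rotation roughly preserves the object's voxel count
  expect_lt(abs(sum(a1$mask$voxels) - sum(ph$truth$voxels)) /
              sum(ph$truth$voxels), 0.25)
})

test_that("training pairs have the documented shapes and sampling guarantees", {
  samples <- generate_dataset(3, small_phantom_spec(), seed = 21)
  tp <- make_training_pairs(samples, fixed_size = 16, patch_size = 16,
                            patches_per_sample = 4, fg_fraction = 1,
                            seed = 2)
  expect_length(tp$coarse, 3L)
  expect_length(tp$fine, 12L)
  for (pr in tp$coarse) {
    expect_identical(dim(pr$x), c(16L, 16L, 16L))
    expect_identical(dim(pr$y), c(16L, 16L, 16L))
    expect_true(all(pr$y %in% c(0L, 1L)))
  }
  # foreground-only sampling: every patch mask has at least one sinus voxel
  for (pr in tp$fine) expect_gt(sum(pr$y), 0)

  tp2 <- make_training_pairs(samples, fixed_size = 16, patch_size = 16,
                             patches_per_sample = 4, fg_fraction = 1,
                             seed = 2)
  expect_identical(tp, tp2)
  expect_error(make_training_pairs(samples, fixed_size = 16, patch_size = 64),
               "exceeds")
})

test_that("training reduces the loss and is reproducible from its seed", {
  samples <- generate_dataset(4, small_phantom_spec(grid = 24L),
                              jitter = small_jitter, seed = 31)
  tp <- make_training_pairs(samples[1:3], fixed_size = 24, patch_size = 24,
                            patches_per_sample = 1, seed = 3)
  vp <- make_training_pairs(samples[4], fixed_size = 24, patch_size = 24,
                            patches_per_sample = 1, seed = 4)
  cfg <- train_config(max_epochs = 3, patience = 3, seed = 5,
                      augment = list(prob = 0))
  net0 <- build_network(network_spec(2), seed = 8)
  r1 <- train_network(net0, tp$coarse, vp$coarse, cfg)
  expect_lt(r1$history$train_loss[nrow(r1$history)], r1$history$train_loss[1])
  r2 <- train_network(net0, tp$coarse, vp$coarse, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$net$params, r2$net$params)
  expect_error(train_network(net0, list(), vp$coarse, cfg), "non-empty")
})

test_that("patience 0 stops at the first epoch without improvement", {
  samples <- generate_dataset(3, small_phantom_spec(grid = 16L, noise_sd = 80),
                              jitter = list(thickening_fraction = 0), seed = 41)
  tp <- make_training_pairs(samples[1:2], fixed_size = 16, patch_size = 16,
                            patches_per_sample = 1, seed = 3)
  vp <- make_training_pairs(samples[3], fixed_size = 16, patch_size = 16,
                            patches_per_sample = 1, seed = 4)
  cfg <- train_config(max_epochs = 30, patience = 0, seed = 6,
                      augment = list(prob = 0.8))
  r <- train_network(build_network(network_spec(2), seed = 9),
                     tp$coarse, vp$coarse, cfg)
  h <- r$history
  worse <- which(diff(cummin(h$val_loss)) == 0)  # epochs with no new best
  if (length(worse) > 0) {
    expect_identical(attr(h, "stop_epoch"), as.integer(min(worse) + 1))
    expect_identical(nrow(h), min(worse) + 1L)
  } else {
    expect_identical(attr(h, "stop_epoch"), cfg$max_epochs)
  }
  # returned weights are those of the best validation epoch
  expect_identical(attr(h, "best_epoch"), which.min(h$val_loss))
})

test_that("per-batch positive weight defaults to capped inverse frequency", {
  ss <- asNamespace("sinusseg")
  y <- array(0L, c(4, 4, 4)); y[1:2] <- 1L
  expect_equal(ss$batch_pos_weight(y, NULL), (64 - 2) / 2)
  expect_equal(ss$batch_pos_weight(array(0L, c(4, 4, 4)), NULL), 1)
  y1 <- array(0L, c(10, 10, 10)); y1[1] <- 1L
  expect_equal(ss$batch_pos_weight(y1, NULL), 100)   # capped
  expect_equal(ss$batch_pos_weight(y, 7), 7)
})
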