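test_that("confusion counts match voxel enumeration", {
  truth <- array(0L, c(2, 2, 1))
  truth[1, 1, 1] <- 1L; truth[2, 1, 1] <- 1L; truth[1, 2, 1] <- 1L
  pred <- array(0L, c(2, 2, 1))
  pred[2, 1, 1] <- 1L; pred[1, 2, 1] <- 1L; pred[2, 2, 1] <- 1L
  cc <- confusion_counts(pred, truth)
  expect_identical(cc, list(TP = 2L, TN = 0L, FP = 1L, FN = 1L))

  m <- random_mask_array(c(4, 4, 4))
  expect_identical(confusion_counts(m, m)[c("FP", "FN")], list(FP = 0L, FN = 0L))
  expect_identical(confusion_counts(1L - m, m)[c("TP", "TN")], list(TP = 0L, TN = 0L))
  expect_error(confusion_counts(m, random_mask_array(c(4, 4, 2))), "shape")
})

test_that("dsc and iou match set-arithmetic brute force on small random pairs", {
  set.seed(101)
  for (i in 1:300) {
    d <- sample(2:6, 3, replace = TRUE)
    a <- random_mask_array(d, p = runif(1, 0.2, 0.8))
    b <- random_mask_array(d, p = runif(1, 0.2, 0.8))
    if (sum(a) + sum(b) == 0) next
    inter <- sum(a == 1L & b == 1L)
    uni <- sum(a == 1L | b == 1L)
    expect_identical(dsc(a, b), 2 * inter / (sum(a) + sum(b)))
    expect_identical(iou(a, b), inter / uni)
  }
})

test_that("dsc worked example and edge cases", {
  # |X| = 3, |Y| = 2, |X intersect Y| = 2 -> 0.8
  x <- array(0L, c(3, 1, 1)); x[1:3, 1, 1] <- 1L
  y <- array(0L, c(3, 1, 1)); y[1:2, 1, 1] <- 1L
  expect_equal(dsc(x, y), 0.8)
  expect_equal(dsc(y, x), 0.8)
  m <- random_mask_array(c(3, 3, 3), 0.6)
  expect_equal(dsc(m, m), 1)
  expect_equal(iou(m, m), 1)
  a <- array(c(1L, 0L), c(2, 1, 1)); b <- array(c(0L, 1L), c(2, 1, 1))
  expect_equal(dsc(a, b), 0)
  z <- array(0L, c(2, 2, 2))
  expect_warning(v <- dsc(z, z), "empty")
  expect_equal(v, 1)
})

test_that("dsc equals 2*iou/(1+iou) to 1e-12 on 1000 random pairs", {
  set.seed(202)
  checked <- 0
  while (checked < 1000) {
    d <- sample(2:6, 3, replace = TRUE)
    a <- random_mask_array(d, runif(1, 0.1, 0.9))
    b <- random_mask_array(d, runif(1, 0.1, 0.9))
    if (sum(a) + sum(b) == 0) next
    expect_lt(abs(dsc(a, b) - 2 * iou(a, b) / (1 + iou(a, b))), 1e-12)
    checked <- checked + 1
  }
})

test_that("hd95 matches brute-force closest-point distances", {
  # two single voxels 3 apart along x at 0.5 mm spacing -> 1.5 mm
  a <- array(0L, c(6, 3, 3)); a[1, 2, 2] <- 1L
  b <- array(0L, c(6, 3, 3)); b[4, 2, 2] <- 1L
  expect_equal(hd95(a, b, spacing = 0.5), 1.5)
  expect_equal(hd95(b, a, spacing = 0.5), 1.5)

  set.seed(303)
  for (i in 1:40) {
    d <- sample(3:6, 3, replace = TRUE)
    sp <- runif(1, 0.3, 1.2)
    a <- random_mask_array(d, 0.4); b <- random_mask_array(d, 0.4)
    if (sum(a) == 0 || sum(b) == 0) next
    or <- hausdorff_oracle(a, b, rep(sp, 3))
    got <- hd95(a, b, spacing = sp)
    expect_equal(got, unname(quantile(or$pooled, 0.95, type = 7)),
                 tolerance = 1e-9)
    expect_lte(got, or$exact_hd + 1e-12)
    # full percentile equals the exact Hausdorff
    expect_equal(hd95(a, b, spacing = sp, percentile = 100), or$exact_hd,
                 tolerance = 1e-9)
  }
})

test_that("hd95 is zero on identical masks and symmetric", {
  m <- random_mask_array(c(5, 5, 5), 0.4)
  m[1, 1, 1] <- 1L
  expect_equal(hd95(m, m, spacing = 0.7), 0)
  a <- random_mask_array(c(5, 5, 5), 0.4); a[2, 2, 2] <- 1L
  expect_equal(hd95(a, m, spacing = 0.7), hd95(m, a, spacing = 0.7))
  expect_error(hd95(array(0L, c(3, 3, 3)), m, spacing = 1), "non-empty")
})

test_that("rms distance follows the printed formula and closed forms", {
  # hand evaluation of sqrt(mean of squares)
  ss <- asNamespace("sinusseg")
  expect_equal(ss$rms_of(c(1, 2, 3)), sqrt((1 + 4 + 9) / 3))

  m <- cube_mesh()
  expect_equal(rms_distance(m, m), 0)

  # plane offset by 0.25 mm along its normal -> exactly 0.25 mm
  grid <- expand.grid(x = 0:3, y = 0:3)
  v0 <- cbind(grid$x, grid$y, 0)
  idx <- function(i, j) (j - 1) * 4 + i
  f <- NULL
  for (j in 1:3) for (i in 1:3)
    f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
               c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  plane0 <- surface_mesh(v0, f)
  plane1 <- surface_mesh(cbind(grid$x, grid$y, 0.25), f)
  expect_equal(rms_distance(plane0, plane1), 0.25)
  # closest point is point-to-triangle, not vertex-to-vertex: points over the
  # interior of a face are still exactly 0.25 away
  pts <- cbind(c(0.5, 1.3, 2.2), c(0.7, 1.9, 2.5), 0.25)
  d <- ss$.cpp_point_mesh_dists(pts, plane0$vertices, plane0$faces - 1L)
  expect_equal(d, rep(0.25, 3))
})

test_that("evaluate_pair and batch stats are internally consistent", {
  spec <- small_phantom_spec(seed = 5)
  s <- generate_phantom(spec)
  pred <- s$truth
  rep1 <- evaluate_pair(pred, s$truth)
  expect_equal(rep1$dsc, 1)
  expect_equal(rep1$iou, 1)
  expect_equal(rep1$hd95_mm, 0)
  expect_identical(rep1$TP + rep1$TN + rep1$FP + rep1$FN,
                   as.integer(prod(dim(s$truth$voxels))))

  # perturb: flip a boundary voxel region
  p2 <- s$truth
  p2$voxels[1:4, 1:4, 1:4] <- 1L
  rep2 <- evaluate_pair(p2, s$truth)
  expect_lt(abs(rep2$dsc - 2 * rep2$iou / (1 + rep2$iou)), 1e-12)
  expect_lte(rep2$iou, rep2$dsc)

  ev <- evaluate_batch(list(list(pred = pred, truth = s$truth),
                            list(pred = pred, truth = s$truth)))
  sm <- ev$summary
  expect_equal(sm$mean[sm$metric == "dsc"], 1)
  expect_equal(sm$sd[sm$metric == "dsc"], 0)
  ev1 <- evaluate_batch(list(list(pred = p2, truth = s$truth)))
  expect_equal(ev1$summary$mean, ev1$summary$min)
  expect_equal(ev1$summary$mean, ev1$summary$max)
})

test_that("growing pred toward truth never decreases dsc", {
  set.seed(404)
  truth <- random_mask_array(c(5, 5, 5), 0.5)
  pred <- truth; fn <- which(pred == 1L)
  drop <- sample(fn, length(fn) %/% 2)
  pred[drop] <- 0L
  d0 <- dsc(pred, truth)
  for (v in drop) {
    pred[v] <- 1L
    d1 <- dsc(pred, truth)
    expect_gte(d1, d0)
    d0 <- d1
  }
  expect_equal(d0, 1)
})
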