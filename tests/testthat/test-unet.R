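test_that("network output matches input shape with values in (0, 1)", {
  net <- build_network(network_spec(base_channels = 2), seed = 1)
  x <- array(runif(16^3, -1000, 400), c(16, 16, 16))
  p <- predict_volume(net, x)
  expect_identical(dim(p), dim(x))
  expect_true(all(p > 0 & p < 1))
  expect_error(predict_volume(net, array(0, c(20, 20, 20))), "divisible by 8")
  xbad <- x; xbad[1] <- NA
  expect_error(predict_volume(net, xbad), "finite")
})

test_that("building and predicting are deterministic given the seed", {
  a <- build_network(network_spec(2), seed = 5)
  b <- build_network(network_spec(2), seed = 5)
  expect_identical(a$params, b$params)
  c_ <- build_network(network_spec(2), seed = 6)
  expect_false(identical(a$params, c_$params))
  x <- array(runif(8^3, -500, 500), c(8, 8, 8))
  expect_identical(predict_volume(a, x), predict_volume(b, x))
  expect_identical(predict_volume(a, x), predict_volume(a, x))
})

test_that("a zeroed head yields probability exactly 0.5", {
  net <- constant_net(0.5)
  x <- array(0, c(8, 8, 8))
  expect_true(all(predict_volume(net, x) == 0.5))
})

test_that("parameter count is a pure function of the architecture spec", {
  # frozen regression value for the desk-scale default (base_channels 8)
  expect_identical(network_n_params(network_spec(8)), 365889)
  for (bc in c(2, 4)) {
    net <- build_network(network_spec(bc), seed = 1)
    expect_identical(sum(vapply(net$params, length, integer(1))),
                     as.integer(network_n_params(network_spec(bc))))
  }
})

test_that("encoder path downsamples by exactly 8 per dimension", {
  ss <- asNamespace("sinusseg")
  net <- build_network(network_spec(2), seed = 2)
  x <- array(runif(16 * 24 * 32), c(16L, 24L, 32L))
  fw <- ss$unet_forward(net, x, keep_cache = TRUE)
  bottleneck_dims <- fw$cache$e4$cache$dims
  expect_identical(bottleneck_dims, c(16L, 24L, 32L) %/% 8L)
})

test_that("backpropagation matches finite differences", {
  withr::local_options(sinusseg.conv_double = TRUE)
  ss <- asNamespace("sinusseg")
  set.seed(42)
  net <- build_network(network_spec(base_channels = 2, n_groups = 2), seed = 7)
  x <- array(runif(8^3), c(8, 8, 8))
  y <- as.vector(array(as.integer(runif(8^3) > 0.8), c(8, 8, 8)))
  w <- 3
  fw <- ss$unet_forward(net, x, keep_cache = TRUE)
  p <- pmin(1 - 1e-7, pmax(1e-7, as.vector(fw$prob)))
  dz <- ((1 - y) * p - w * y * (1 - p)) / length(y)
  grads <- ss$unet_backward(net, fw$cache, dz)
  loss_fn <- function(params) {
    pr <- as.vector(ss$unet_forward(list(spec = net$spec, params = params), x)$prob)
    pr <- pmin(1 - 1e-7, pmax(1e-7, pr))
    -mean(w * y * log(pr) + (1 - y) * log(1 - pr))
  }
  eps <- 1e-5
  for (nm in c("enc1.W1", "enc2.g1", "dec3.W2", "dec1.W1", "out.W", "out.b",
               "enc3.be2")) {
    for (i in sample(length(net$params[[nm]]), min(3, length(net$params[[nm]])))) {
      pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-6 + 1e-3 * (abs(num) + abs(ana)))
    }
  }
})

test_that("checkpoints round trip and refuse a mismatched architecture", {
  net <- build_network(network_spec(2), seed = 3)
  f <- tempfile(fileext = ".rds")
  hist <- data.frame(epoch = 1, train_loss = 0.5, val_loss = 0.6)
  save_checkpoint(net, f, history = hist)
  r <- load_checkpoint(f, expected_spec = network_spec(2))
  expect_identical(r$params, net$params)
  expect_identical(attr(r, "history"), hist)
  expect_error(load_checkpoint(f, expected_spec = network_spec(4)),
               "does not match")
  saveRDS(list(a = 1), f)
  expect_error(load_checkpoint(f), "not a network checkpoint")
})
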