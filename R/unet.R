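#' 3D U-Net architecture specification
#'
#' Fixes the segmentation network family used by both pipeline stages: 4
#' encoder blocks and 3 decoder blocks, two 3x3x3 convolutions per block,
#' each followed by group normalization (8 groups by default) and a ReLU;
#' 2x2x2 max pooling (stride 2) after each of the first three encoders, so
#' the spatial size halves exactly three times and input extents must be
#' divisible by 8. Decoders upsample trilinearly, concatenate the matching
#' encoder feature map (skip connection) and convolve; a final 1x1x1
#' convolution and logistic squashing yield a per-voxel probability in (0,1).
#' Channel widths per level are `base_channels * c(1, 2, 4, 8)`.
#'
#' Input intensities are linearly mapped from the fixed `hu_window` to
#' \[0, 1\] (clamped) before entering the network, which keeps inference
#' deterministic across scans with different intensity ranges.
#'
#' @param base_channels Width multiplier (first-level channels). The desk
#'   scale default of 8 keeps CPU training tractable.
#' @param n_groups Number of group-normalization groups (reduced per layer to
#'   the largest divisor of the channel count when needed).
#' @param hu_window Length-2 HU window mapped to \[0, 1\].
#' @return A `unet_spec` list.
#' @export
network_spec <- function(base_channels = 8, n_groups = 8,
                         hu_window = c(-1000, 400)) {
  if (base_channels < 1) stop("base_channels must be >= 1")
  structure(list(n_encoders = 4L, n_decoders = 3L, kernel = 3L,
                 base_channels = as.integer(base_channels),
                 n_groups = as.integer(n_groups),
                 hu_window = as.numeric(hu_window)),
            class = "unet_spec")
}

# block topology: channel counts derive from the spec
unet_blocks <- function(spec) {
  b <- spec$base_channels
  w <- b * c(1L, 2L, 4L, 8L)
  list(enc1 = c(1L, w[1]), enc2 = c(w[1], w[2]), enc3 = c(w[2], w[3]),
       enc4 = c(w[3], w[4]),
       dec3 = c(w[4] + w[3], w[3]), dec2 = c(w[3] + w[2], w[2]),
       dec1 = c(w[2] + w[1], w[1]))
}

gn_groups <- function(channels, n_groups) {
  g <- min(n_groups, channels)
  while (channels %% g != 0L) g <- g - 1L
  g
}

#' Build a randomly initialized 3D U-Net
#'
#' Convolution weights use He-normal initialization (sd `sqrt(2 / fan_in)`),
#' biases start at zero, and group-norm scales/offsets at 1/0. Initialization
#' is deterministic given `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the weight draw.
#' @return A `sinus_unet` with elements `spec`, `params` (flat named list of
#'   arrays) and `seed`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  blocks <- unet_blocks(spec)
  params <- with_seed(seed, {
    p <- list()
    for (nm in names(blocks)) {
      cin <- blocks[[nm]][1]; cout <- blocks[[nm]][2]
      p[[paste0(nm, ".W1")]] <- matrix(rnorm(cout * 27 * cin, sd = sqrt(2 / (27 * cin))),
                                       nrow = cout)
      p[[paste0(nm, ".b1")]] <- numeric(cout)
      p[[paste0(nm, ".g1")]] <- rep(1, cout)
      p[[paste0(nm, ".be1")]] <- numeric(cout)
      p[[paste0(nm, ".W2")]] <- matrix(rnorm(cout * 27 * cout, sd = sqrt(2 / (27 * cout))),
                                       nrow = cout)
      p[[paste0(nm, ".b2")]] <- numeric(cout)
      p[[paste0(nm, ".g2")]] <- rep(1, cout)
      p[[paste0(nm, ".be2")]] <- numeric(cout)
    }
    p[["out.W"]] <- matrix(rnorm(spec$base_channels, sd = sqrt(2 / spec$base_channels)),
                           nrow = 1)
    # background prior: start the head biased toward "not sinus", the usual
    # initialization for heavily class-imbalanced segmentation
    p[["out.b"]] <- -2
    p
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "sinus_unet")
}

#' @export
print.sinus_unet <- function(x, ...) {
  cat("<sinus_unet> base_channels ", x$spec$base_channels, ", ",
      format(network_n_params(x$spec), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters implied by a network spec
#'
#' A pure function of the architecture; used as a regression guard.
#'
#' @param spec A `unet_spec`.
#' @return Integer parameter count.
#' @export
network_n_params <- function(spec) {
  blocks <- unet_blocks(spec)
  n <- 0
  for (nm in names(blocks)) {
    cin <- blocks[[nm]][1]; cout <- blocks[[nm]][2]
    n <- n + cout * 27 * cin + cout +        # conv1
      2 * cout +                             # gn1
      cout * 27 * cout + cout +              # conv2
      2 * cout                               # gn2
  }
  n + spec$base_channels + 1                 # 1x1x1 head
}

GN_EPS <- 1e-5

# one conv -> GN -> ReLU -> conv -> GN -> ReLU block; x is C x N
conv_exact <- function() isTRUE(getOption("sinusseg.conv_double"))

block_forward <- function(params, nm, x, dims, n_groups) {
  g1 <- gn_groups(length(params[[paste0(nm, ".b1")]]), n_groups)
  ex <- conv_exact()
  c1 <- .cpp_conv3d_fwd(x, dims, params[[paste0(nm, ".W1")]], params[[paste0(nm, ".b1")]], ex)
  n1 <- .cpp_groupnorm_fwd(c1, g1, params[[paste0(nm, ".g1")]],
                           params[[paste0(nm, ".be1")]], GN_EPS)
  r1 <- n1$out * (n1$out > 0)
  c2 <- .cpp_conv3d_fwd(r1, dims, params[[paste0(nm, ".W2")]], params[[paste0(nm, ".b2")]], ex)
  n2 <- .cpp_groupnorm_fwd(c2, g1, params[[paste0(nm, ".g2")]],
                           params[[paste0(nm, ".be2")]], GN_EPS)
  out <- n2$out * (n2$out > 0)
  list(out = out,
       cache = list(x = x, dims = dims, c1 = c1, m1 = n1$mean, v1 = n1$invstd,
                    r1 = r1, c2 = c2, m2 = n2$mean, v2 = n2$invstd,
                    gn_out1 = n1$out, gn_out2 = n2$out, groups = g1))
}

block_backward <- function(params, nm, cache, dout, grads) {
  g <- cache$groups
  ex <- conv_exact()
  dout <- dout * (cache$gn_out2 > 0)
  gn2 <- .cpp_groupnorm_bwd(cache$c2, dout, g, params[[paste0(nm, ".g2")]],
                            cache$m2, cache$v2)
  grads[[paste0(nm, ".g2")]] <- gn2$dgamma
  grads[[paste0(nm, ".be2")]] <- gn2$dbeta
  cv2 <- .cpp_conv3d_bwd(cache$r1, cache$dims, params[[paste0(nm, ".W2")]], gn2$dx, ex)
  grads[[paste0(nm, ".W2")]] <- cv2$dW
  grads[[paste0(nm, ".b2")]] <- cv2$db
  dr1 <- cv2$dx * (cache$gn_out1 > 0)
  gn1 <- .cpp_groupnorm_bwd(cache$c1, dr1, g, params[[paste0(nm, ".g1")]],
                            cache$m1, cache$v1)
  grads[[paste0(nm, ".g1")]] <- gn1$dgamma
  grads[[paste0(nm, ".be1")]] <- gn1$dbeta
  cv1 <- .cpp_conv3d_bwd(cache$x, cache$dims, params[[paste0(nm, ".W1")]], gn1$dx, ex)
  grads[[paste0(nm, ".W1")]] <- cv1$dW
  grads[[paste0(nm, ".b1")]] <- cv1$db
  list(dx = cv1$dx, grads = grads)
}

check_divisible <- function(dims) {
  if (any(dims %% 8L != 0L))
    stop("input spatial dimensions (", paste(dims, collapse = "x"),
         ") must each be divisible by 8 (three 2x down-samplings)")
}

# Full forward pass. x is a 3D array of NORMALIZED intensities in [0, 1].
# Returns the probability array and (optionally) every intermediate needed
# for backpropagation.
unet_forward <- function(net, x, keep_cache = FALSE) {
  dims <- dim(x)
  check_divisible(dims)
  p <- net$params
  ng <- net$spec$n_groups
  x1 <- matrix(as.double(x), nrow = 1)
  e1 <- block_forward(p, "enc1", x1, dims, ng)
  p1 <- .cpp_maxpool_fwd(e1$out, dims); dims2 <- dims %/% 2L
  e2 <- block_forward(p, "enc2", p1$out, dims2, ng)
  p2 <- .cpp_maxpool_fwd(e2$out, dims2); dims4 <- dims2 %/% 2L
  e3 <- block_forward(p, "enc3", p2$out, dims4, ng)
  p3 <- .cpp_maxpool_fwd(e3$out, dims4); dims8 <- dims4 %/% 2L
  e4 <- block_forward(p, "enc4", p3$out, dims8, ng)
  u3 <- .cpp_upsample2_fwd(e4$out, dims8)
  d3 <- block_forward(p, "dec3", rbind(u3, e3$out), dims4, ng)
  u2 <- .cpp_upsample2_fwd(d3$out, dims4)
  d2 <- block_forward(p, "dec2", rbind(u2, e2$out), dims2, ng)
  u1 <- .cpp_upsample2_fwd(d2$out, dims2)
  d1 <- block_forward(p, "dec1", rbind(u1, e1$out), dims, ng)
  z <- as.vector(p[["out.W"]] %*% d1$out) + p[["out.b"]]
  prob <- array(1 / (1 + exp(-z)), dims)
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob,
       cache = list(dims = dims, e1 = e1, p1 = p1, e2 = e2, p2 = p2, e3 = e3,
                    p3 = p3, e4 = e4, d3 = d3, d2 = d2, d1 = d1,
                    d1out = d1$out))
}

# Backward pass from dL/dz (logit gradient, length N vector).
unet_backward <- function(net, cache, dz) {
  p <- net$params
  grads <- list()
  dims <- cache$dims; dims2 <- dims %/% 2L; dims4 <- dims2 %/% 2L; dims8 <- dims4 %/% 2L
  dzm <- matrix(dz, nrow = 1)
  grads[["out.W"]] <- dzm %*% t(cache$d1out)
  grads[["out.b"]] <- sum(dz)
  dd1 <- t(p[["out.W"]]) %*% dzm

  bb <- block_backward(p, "dec1", cache$d1$cache, dd1, grads); grads <- bb$grads
  cu1 <- nrow(bb$dx) - nrow(cache$e1$out)  # channels that came from upsampling
  du1 <- bb$dx[seq_len(cu1), , drop = FALSE]
  de1_skip <- bb$dx[(cu1 + 1):nrow(bb$dx), , drop = FALSE]
  dd2 <- .cpp_upsample2_bwd(du1, dims2)

  bb <- block_backward(p, "dec2", cache$d2$cache, dd2, grads); grads <- bb$grads
  cu2 <- nrow(bb$dx) - nrow(cache$e2$out)
  du2 <- bb$dx[seq_len(cu2), , drop = FALSE]
  de2_skip <- bb$dx[(cu2 + 1):nrow(bb$dx), , drop = FALSE]
  dd3 <- .cpp_upsample2_bwd(du2, dims4)

  bb <- block_backward(p, "dec3", cache$d3$cache, dd3, grads); grads <- bb$grads
  cu3 <- nrow(bb$dx) - nrow(cache$e3$out)
  du3 <- bb$dx[seq_len(cu3), , drop = FALSE]
  de3_skip <- bb$dx[(cu3 + 1):nrow(bb$dx), , drop = FALSE]
  de4 <- .cpp_upsample2_bwd(du3, dims8)

  bb <- block_backward(p, "enc4", cache$e4$cache, de4, grads); grads <- bb$grads
  dp3 <- .cpp_maxpool_bwd(bb$dx, cache$p3$argmax, nrow(cache$e3$out), dims4)
  bb <- block_backward(p, "enc3", cache$e3$cache, dp3 + de3_skip, grads); grads <- bb$grads
  dp2 <- .cpp_maxpool_bwd(bb$dx, cache$p2$argmax, nrow(cache$e2$out), dims2)
  bb <- block_backward(p, "enc2", cache$e2$cache, dp2 + de2_skip, grads); grads <- bb$grads
  dp1 <- .cpp_maxpool_bwd(bb$dx, cache$p1$argmax, nrow(cache$e1$out), dims)
  bb <- block_backward(p, "enc1", cache$e1$cache, dp1 + de1_skip, grads); grads <- bb$grads
  grads
}

normalize_hu <- function(x, hu_window) {
  pmin(1, pmax(0, (x - hu_window[1]) / (hu_window[2] - hu_window[1])))
}

#' Predict a probability map for a volume or patch
#'
#' Applies the fixed HU windowing and runs the network in evaluation mode.
#' The computation is a pure function of weights and input, so repeated calls
#' return bit-identical probability maps.
#'
#' @param net A `sinus_unet`.
#' @param v A `sinus_volume` or a 3D array of raw intensities (HU). Each
#'   spatial dimension must be divisible by 8.
#' @return A 3D array of probabilities in (0, 1), same shape as the input.
#' @export
predict_volume <- function(net, v) {
  stopifnot(inherits(net, "sinus_unet"))
  x <- if (inherits(v, "sinus_volume")) v$voxels else v
  if (!is.array(x) || length(dim(x)) != 3L) stop("input must be a 3D array")
  if (!all(is.finite(x))) stop("input voxels must all be finite")
  xn <- array(normalize_hu(x, net$spec$hu_window), dim(x))
  unet_forward(net, xn, keep_cache = FALSE)$prob
}

#' Save and load network checkpoints
#'
#' A checkpoint is self-describing: it carries the architecture spec, the
#' initialization seed and the training history next to the weights.
#' `load_checkpoint()` refuses a file whose architecture does not match the
#' requested spec.
#'
#' @param net A `sinus_unet`.
#' @param path Checkpoint file path (`.rds`).
#' @param history Optional training history to embed.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the `sinus_unet` (with a `history` attribute when present).
#' @export
save_checkpoint <- function(net, path, history = NULL) {
  stopifnot(inherits(net, "sinus_unet"))
  saveRDS(list(spec = net$spec, params = net$params, seed = net$seed,
               history = history, format = "sinusseg-checkpoint-1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_spec Optional `unet_spec` the checkpoint must match.
#' @export
load_checkpoint <- function(path, expected_spec = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$format, "sinusseg-checkpoint-1"))
    stop("not a network checkpoint: ", path)
  if (!is.null(expected_spec) && !identical(unclass(ck$spec), unclass(expected_spec)))
    stop("checkpoint architecture does not match the requested spec")
  net <- structure(list(spec = ck$spec, params = ck$params, seed = ck$seed),
                   class = "sinus_unet")
  attr(net, "history") <- ck$history
  net
}
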