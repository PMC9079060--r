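#' Weighted binary cross-entropy loss
#'
#' The voxel-averaged binary cross-entropy with a multiplier `w` on the
#' positive-class term,
#' `loss = -mean(w * y * log(p) + (1 - y) * log(1 - p))`,
#' the standard form for a heavily class-imbalanced binary mask (the sinus
#' occupies a small fraction of a scan). Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param p Probability array (or `ProbMap`) with values in \[0, 1\].
#' @param y Binary array or `sinus_mask` of the same shape.
#' @param w Non-negative weight on the positive-class term (default 1 =
#'   unweighted BCE).
#' @return Scalar non-negative loss.
#' @export
weighted_bce <- function(p, y, w = 1) {
  if (inherits(y, "sinus_mask")) y <- y$voxels
  if (!identical(dim(p), dim(y)) && length(p) != length(y))
    stop("probability map and mask shapes differ")
  if (w < 0) stop("w must be >= 0")
  pc <- pmin(1 - BCE_EPS, pmax(BCE_EPS, p))
  -mean(w * y * log(pc) + (1 - y) * log(1 - pc))
}

BCE_EPS <- 1e-7

#' Training configuration
#'
#' @param learning_rate ADAM learning rate (default 1.25e-4).
#' @param max_epochs Maximum number of epochs.
#' @param batch_size Samples per gradient step (gradients are averaged).
#' @param patience Epochs without validation-loss improvement before early
#'   stopping; `0` stops at the first non-improving epoch.
#' @param pos_weight Positive-class weight for the loss, or `NULL` to use the
#'   inverse class frequency of each batch, capped at 100.
#' @param augment List of augmentation ranges: `rotation_deg`, `scale`
#'   (fractional), `elastic_sd` (control-point displacement sd, voxels),
#'   `elastic_grid` (control points per axis), `prob` (probability a sample
#'   is augmented). All ranges admit the identity transform.
#' @param seed Integer seed; the whole training run is reproducible from it.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1.25e-4, max_epochs = 30,
                         batch_size = 1, patience = 5, pos_weight = NULL,
                         augment = list(), seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (patience < 0) stop("patience must be >= 0")
  aug <- modifyList(list(rotation_deg = 10, scale = 0.1, elastic_sd = 1,
                         elastic_grid = 4, prob = 0.5), augment)
  structure(list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), patience = as.integer(patience),
                 pos_weight = pos_weight, augment = aug, seed = as.integer(seed)),
            class = "train_config")
}

#' Random spatial augmentation of an image/mask pair
#'
#' Applies one spatial transform — rotation, isotropic scaling and a smooth
#' elastic deformation from a coarse control grid — to both the image
#' (trilinear interpolation) and the mask (nearest neighbour, so the mask
#' stays binary). Identity parameters return the inputs unchanged; given a
#' seed the sampled transform is deterministic.
#'
#' @param v A `sinus_volume`.
#' @param m A `sinus_mask` on the same grid.
#' @param params Optional explicit transform: list with `rotation` (3 Euler
#'   angles, degrees), `scale` (factor) and `elastic` (3 x n-voxel
#'   displacement matrix or `NULL`).
#' @param ranges Augmentation ranges as in [train_config()].
#' @param seed Seed used when `params` is `NULL`.
#' @return List with transformed `volume` and `mask`.
#' @export
augment <- function(v, m, params = NULL, ranges = train_config()$augment,
                    seed = 1L) {
  stopifnot(inherits(v, "sinus_volume"), inherits(m, "sinus_mask"))
  if (!same_geometry(v, m)) stop("volume and mask geometries differ")
  dims <- dim(v$voxels)
  if (is.null(params)) {
    params <- with_seed(seed, {
      list(rotation = runif(3, -ranges$rotation_deg, ranges$rotation_deg),
           scale = runif(1, 1 - ranges$scale, 1 + ranges$scale),
           elastic = sample_elastic_field(dims, ranges$elastic_grid,
                                          ranges$elastic_sd))
    })
  }
  identity_tf <- all(params$rotation == 0) && params$scale == 1 &&
    (is.null(params$elastic) || all(params$elastic == 0))
  if (identity_tf) return(list(volume = v, mask = m))
  ctr <- (dims - 1) / 2
  A <- t(euler_matrix(params$rotation)) / params$scale
  t_off <- ctr - A %*% ctr
  vw <- .cpp_warp_affine(as.double(v$voxels), as.integer(dims), as.integer(dims),
                         A, as.vector(t_off), params$elastic, "linear",
                         fill = v$voxels[1])
  mw <- .cpp_warp_affine(as.double(m$voxels), as.integer(dims), as.integer(dims),
                         A, as.vector(t_off), params$elastic, "nearest", fill = 0)
  list(volume = volume(array(vw, dims), v$spacing, v$origin),
       mask = binary_mask(array(as.integer(mw), dims), like = v))
}

# Smooth displacement field: Gaussian offsets on a coarse control grid,
# trilinearly upsampled to the full grid. Returns 3 x n_voxels or NULL.
sample_elastic_field <- function(dims, grid_n, sd) {
  if (sd <= 0) return(NULL)
  ctrl <- array(rnorm(3 * grid_n^3, sd = sd), c(grid_n, grid_n, grid_n, 3))
  A <- diag((rep(grid_n, 3) - 1) / (dims - 1))
  comp <- lapply(1:3, function(k)
    .cpp_warp_affine(as.double(ctrl[, , , k]), rep(as.integer(grid_n), 3),
                     as.integer(dims), A, c(0, 0, 0), NULL, "linear", 0))
  rbind(as.vector(comp[[1]]), as.vector(comp[[2]]), as.vector(comp[[3]]))
}

#' Build coarse and fine training datasets from phantom samples
#'
#' The coarse dataset pairs each full scan, downsampled to `fixed_size`
#' voxels (trilinear; mask nearest-neighbour), with its downsampled mask —
#' the stage-1 task. The fine dataset holds full-resolution patches of
#' `patch_size`, sampled per scan so that a fraction `fg_fraction` of them is
#' centred on a random sinus voxel (the rest are uniform background patches).
#'
#' @param samples List of `phantom_sample` (or lists with `volume`/`truth`).
#' @param fixed_size Coarse grid size (length 1 or 3; divisible by 8).
#' @param patch_size Fine patch size (length 1 or 3; divisible by 8).
#' @param patches_per_sample Patches drawn from each scan.
#' @param fg_fraction Fraction of patches guaranteed to contain sinus voxels.
#' @param seed Integer seed for patch sampling.
#' @return List with elements `coarse` and `fine`, each a list of
#'   `list(x = HU array, y = binary array)` pairs.
#' @export
make_training_pairs <- function(samples, fixed_size = 32, patch_size = 32,
                                patches_per_sample = 4, fg_fraction = 0.75,
                                seed = 1L) {
  fixed_size <- as.integer(check_len3(fixed_size))
  patch_size <- as.integer(check_len3(patch_size))
  check_divisible(fixed_size)
  check_divisible(patch_size)
  coarse <- lapply(samples, function(s) {
    vol_c <- resample_to_grid(s$volume, fixed_size,
                              s$volume$spacing * dim(s$volume$voxels) / fixed_size,
                              "linear")
    msk_c <- resample_to_grid(s$truth, fixed_size,
                              s$truth$spacing * dim(s$truth$voxels) / fixed_size,
                              "nearest")
    list(x = vol_c$voxels, y = msk_c$voxels)
  })
  fine <- with_seed(derive_seed(seed, 7), {
    out <- list()
    for (s in samples) {
      dims <- dim(s$volume$voxels)
      if (any(patch_size > dims))
        stop("patch size ", paste(patch_size, collapse = "x"),
             " exceeds the volume grid ", paste(dims, collapse = "x"))
      fg_idx <- which(s$truth$voxels == 1L)
      for (k in seq_len(patches_per_sample)) {
        want_fg <- length(fg_idx) > 0 && (k <= round(fg_fraction * patches_per_sample))
        org <- if (want_fg) {
          ctr <- arrayInd(sample(fg_idx, 1), dims)[1, ]
          pmin(pmax(ctr - patch_size %/% 2L, 1L), dims - patch_size + 1L)
        } else {
          vapply(1:3, function(a) sample(dims[a] - patch_size[a] + 1L, 1), integer(1))
        }
        sl <- lapply(1:3, function(a) org[a]:(org[a] + patch_size[a] - 1L))
        out[[length(out) + 1L]] <-
          list(x = s$volume$voxels[sl[[1]], sl[[2]], sl[[3]]],
               y = s$truth$voxels[sl[[1]], sl[[2]], sl[[3]]],
               origin_index = as.integer(org - 1L))
      }
    }
    out
  })
  list(coarse = coarse, fine = fine)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

batch_pos_weight <- function(y, pos_weight, cap = 100) {
  if (!is.null(pos_weight)) return(pos_weight)
  npos <- sum(y)
  if (npos == 0) return(1)
  min(cap, (length(y) - npos) / npos)
}

#' Train a 3D U-Net on image/mask pairs
#'
#' ADAM optimization of the weighted binary cross-entropy, with per-sample
#' random spatial augmentation, per-epoch validation and early stopping: when
#' the validation loss fails to improve for more than `patience` consecutive
#' epochs the run stops and the weights of the best validation epoch are
#' returned. Fully reproducible from `cfg$seed`.
#'
#' @param net A `sinus_unet` (see [build_network()]).
#' @param train_set,val_set Lists of `list(x = HU array, y = binary array)`
#'   pairs, e.g. from [make_training_pairs()]; must be non-empty.
#' @param cfg A [train_config()].
#' @return List with `net` (trained, best-epoch weights) and `history` (one
#'   row per epoch: train loss, validation loss; attributes `stop_epoch`,
#'   `best_epoch`).
#' @export
train_network <- function(net, train_set, val_set, cfg = train_config()) {
  stopifnot(inherits(net, "sinus_unet"), inherits(cfg, "train_config"))
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("training and validation sets must be non-empty")
  params <- net$params
  state <- adam_init(params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  bad_epochs <- 0L; stop_epoch <- cfg$max_epochs
  hw <- net$spec$hu_window

  for (epoch in seq_len(cfg$max_epochs)) {
    eseed <- derive_seed(cfg$seed, epoch)
    order_idx <- with_seed(eseed, sample(length(train_set)))
    tot_loss <- 0
    n_batches <- 0L
    i <- 1L
    while (i <= length(order_idx)) {
      take <- order_idx[i:min(i + cfg$batch_size - 1L, length(order_idx))]
      i <- i + cfg$batch_size
      acc <- NULL
      batch_loss <- 0
      for (j in seq_along(take)) {
        item <- train_set[[take[j]]]
        pair <- maybe_augment(item, cfg, derive_seed(eseed, take[j]))
        xn <- array(normalize_hu(pair$x, hw), dim(pair$x))
        fw <- unet_forward(list(spec = net$spec, params = params), xn,
                           keep_cache = TRUE)
        w <- batch_pos_weight(pair$y, cfg$pos_weight)
        loss <- weighted_bce(fw$prob, pair$y, w)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch)
        batch_loss <- batch_loss + loss
        p <- as.vector(fw$prob); y <- as.vector(pair$y)
        pc <- pmin(1 - BCE_EPS, pmax(BCE_EPS, p))
        dz <- ((1 - y) * pc - w * y * (1 - pc)) / length(y)
        g <- unet_backward(list(spec = net$spec, params = params), fw$cache, dz)
        acc <- if (is.null(acc)) g else Map(`+`, acc, g)
      }
      if (length(take) > 1L) acc <- lapply(acc, function(g) g / length(take))
      st <- adam_step(params, acc, state, cfg$learning_rate)
      params <- st$params; state <- st$state
      tot_loss <- tot_loss + batch_loss / length(take)
      n_batches <- n_batches + 1L
    }
    train_loss <- tot_loss / n_batches
    val_loss <- mean(vapply(val_set, function(item) {
      xn <- array(normalize_hu(item$x, hw), dim(item$x))
      pr <- unet_forward(list(spec = net$spec, params = params), xn)$prob
      weighted_bce(pr, item$y, batch_pos_weight(item$y, cfg$pos_weight))
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss; best_params <- params; best_epoch <- epoch
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs > cfg$patience) { stop_epoch <- epoch; break }
    }
    stop_epoch <- epoch
  }
  out_net <- structure(list(spec = net$spec, params = best_params,
                            seed = net$seed), class = "sinus_unet")
  attr(hist, "stop_epoch") <- stop_epoch
  attr(hist, "best_epoch") <- best_epoch
  attr(hist, "best_val") <- best_val
  list(net = out_net, history = hist)
}

maybe_augment <- function(item, cfg, seed) {
  do_aug <- with_seed(derive_seed(seed, 3), runif(1)) < cfg$augment$prob
  if (!do_aug) return(list(x = item$x, y = item$y))
  v <- volume(item$x, spacing = 1)
  m <- binary_mask(item$y, like = v)
  a <- augment(v, m, ranges = cfg$augment, seed = derive_seed(seed, 4))
  list(x = a$volume$voxels, y = a$mask$voxels)
}
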