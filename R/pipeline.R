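#' Pipeline configuration
#'
#' Desk-scale defaults: 0.4 mm working resolution, a 32^3 coarse grid, 32^3
#' fine patches with 16^3 stride (50% overlap), probability threshold 0.5,
#' and 10 iterations of volume-preserving mesh smoothing. All grid sizes must
#' be divisible by 8 (the network's downsampling factor).
#'
#' @param target_spacing Working isotropic voxel size (mm).
#' @param coarse_fixed_size Grid the scan is downsampled to for stage 1.
#' @param patch_size,patch_stride Fine-stage patch tiling (stride <= size).
#' @param prob_threshold Binarization threshold in (0, 1).
#' @param bbox_margin_voxels Margin added around the coarse foreground
#'   bounding box before patch tiling, so stage 2 sees the full sinus even if
#'   stage 1 slightly under-segments.
#' @param smoothing List: `method` (`"taubin"` or `"none"`), `iterations`,
#'   `lambda`, `mu`.
#' @param min_component_voxels Components smaller than this never count as a
#'   valid prediction (floor for the failure flag).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(target_spacing = 0.4,
                            coarse_fixed_size = 32,
                            patch_size = 32,
                            patch_stride = 16,
                            prob_threshold = 0.5,
                            bbox_margin_voxels = 4,
                            smoothing = list(),
                            min_component_voxels = 1) {
  smoothing <- modifyList(list(method = "taubin", iterations = 10,
                               lambda = 0.5, mu = -0.53), smoothing)
  cfg <- list(target_spacing = target_spacing,
              coarse_fixed_size = as.integer(check_len3(coarse_fixed_size)),
              patch_size = as.integer(check_len3(patch_size)),
              patch_stride = as.integer(check_len3(patch_stride)),
              prob_threshold = prob_threshold,
              bbox_margin_voxels = as.integer(bbox_margin_voxels),
              smoothing = smoothing,
              min_component_voxels = as.integer(min_component_voxels))
  if (cfg$prob_threshold <= 0 || cfg$prob_threshold >= 1)
    stop("prob_threshold must be in (0, 1)")
  if (any(cfg$patch_stride > cfg$patch_size))
    stop("patch_stride must not exceed patch_size")
  if (any(cfg$coarse_fixed_size %% 8L != 0L))
    stop("coarse_fixed_size must be divisible by 8")
  check_divisible(cfg$patch_size)
  structure(cfg, class = "pipeline_config")
}

#' Stage 1: low-resolution segmentation on the full grid
#'
#' Downsamples the (already isotropically resampled) volume to the fixed
#' coarse grid, runs the coarse network, and trilinearly upsamples the
#' probability map back to the input grid.
#'
#' @param v A `sinus_volume` at the working resolution.
#' @param coarse_net Trained `sinus_unet` for stage 1.
#' @param cfg A [pipeline_config()].
#' @return Probability array on the full grid, values in \[0, 1\].
#' @export
coarse_segment <- function(v, coarse_net, cfg = pipeline_config()) {
  stopifnot(inherits(v, "sinus_volume"))
  dims <- dim(v$voxels)
  small <- resample_to_grid(v, cfg$coarse_fixed_size,
                            v$spacing * dims / cfg$coarse_fixed_size, "linear")
  prob_small <- predict_volume(coarse_net, small)
  # back to the full grid with the same centre-aligned mapping
  scale <- cfg$coarse_fixed_size / dims
  A <- diag(scale)
  t <- (cfg$coarse_fixed_size - 1) / 2 - scale * (dims - 1) / 2
  arr <- .cpp_warp_affine(as.double(prob_small), as.integer(cfg$coarse_fixed_size),
                          as.integer(dims), A, t, NULL, "linear", fill = 0)
  array(pmin(1, pmax(0, arr)), dims)
}

#' Stage 2 patch proposal from the coarse probability map
#'
#' Thresholds the coarse map, takes the bounding box of the foreground
#' (inflated by `bbox_margin_voxels`), tiles it with patches of
#' `cfg$patch_size` at `cfg$patch_stride`, shifts any patch sticking out of
#' the grid back inside (origins move, sizes never shrink), and keeps the
#' patches that intersect the thresholded foreground. Patches are ordered
#' lexicographically by origin.
#'
#' @param coarse Probability array on the full grid.
#' @param cfg A [pipeline_config()].
#' @return List of patches, each `list(origin_index, size)` with 0-based
#'   `origin_index`; empty list when nothing is above threshold.
#' @export
propose_patches <- function(coarse, cfg = pipeline_config()) {
  dims <- dim(coarse)
  if (any(cfg$patch_size > dims))
    stop("patch size exceeds the volume grid")
  fg <- which(coarse >= cfg$prob_threshold)
  if (length(fg) == 0L) return(list())
  ind <- arrayInd(fg, dims)
  lo <- pmax(apply(ind, 2, min) - cfg$bbox_margin_voxels, 1L)
  hi <- pmin(apply(ind, 2, max) + cfg$bbox_margin_voxels, dims)
  starts <- lapply(1:3, function(a) {
    s <- seq.int(lo[a], by = cfg$patch_stride[a],
                 length.out = max(1L, ceiling((hi[a] - lo[a] + 1 - cfg$patch_size[a]) /
                                                cfg$patch_stride[a]) + 1L))
    pmin(pmax(s, 1L), dims[a] - cfg$patch_size[a] + 1L)
  })
  grid <- expand.grid(x = unique(starts[[1]]), y = unique(starts[[2]]),
                      z = unique(starts[[3]]))
  grid <- grid[order(grid$x, grid$y, grid$z), , drop = FALSE]
  fgset <- array(FALSE, dims)
  fgset[fg] <- TRUE
  out <- list()
  for (i in seq_len(nrow(grid))) {
    org <- as.integer(grid[i, ])
    sl <- lapply(1:3, function(a) org[a]:(org[a] + cfg$patch_size[a] - 1L))
    if (any(fgset[sl[[1]], sl[[2]], sl[[3]]]))
      out[[length(out) + 1L]] <- list(origin_index = org - 1L,
                                      size = cfg$patch_size)
  }
  out
}

#' Stage 2: predict each patch and stitch the full-resolution map
#'
#' Each proposed patch is predicted independently by the fine network;
#' overlapping voxels receive the arithmetic mean of all contributing
#' predictions and voxels covered by no patch get probability 0.
#'
#' @param v A `sinus_volume` at the working resolution.
#' @param patches Patch list from [propose_patches()].
#' @param fine_net Trained `sinus_unet` for stage 2.
#' @param cfg A [pipeline_config()].
#' @return Probability array on the full grid.
#' @export
fine_segment_and_stitch <- function(v, patches, fine_net, cfg = pipeline_config()) {
  stopifnot(inherits(v, "sinus_volume"))
  dims <- dim(v$voxels)
  acc <- array(0, dims)
  cnt <- array(0L, dims)
  for (p in patches) {
    org <- p$origin_index + 1L
    sl <- lapply(1:3, function(a) org[a]:(org[a] + p$size[a] - 1L))
    patch <- v$voxels[sl[[1]], sl[[2]], sl[[3]]]
    pr <- predict_volume(fine_net, patch)
    acc[sl[[1]], sl[[2]], sl[[3]]] <- acc[sl[[1]], sl[[2]], sl[[3]]] + pr
    cnt[sl[[1]], sl[[2]], sl[[3]]] <- cnt[sl[[1]], sl[[2]], sl[[3]]] + 1L
  }
  covered <- cnt > 0L
  acc[covered] <- acc[covered] / cnt[covered]
  acc
}

#' Binarize a probability map and keep the largest connected component
#'
#' Thresholds at `cfg$prob_threshold` (`>=` is foreground) and keeps the
#' single largest 26-connected component; ties go to the component containing
#' the lexicographically smallest voxel index. An empty result (nothing above
#' threshold, or largest component below `min_component_voxels`) returns an
#' empty mask flagged as a failed prediction.
#'
#' @param p Probability array.
#' @param cfg A [pipeline_config()].
#' @param like Optional `sinus_volume` supplying the output geometry.
#' @return A `sinus_mask` with attributes `failed` (logical) and
#'   `component_sizes` (voxel counts of all components before selection).
#' @export
postprocess_prob <- function(p, cfg = pipeline_config(), like = NULL) {
  dims <- dim(p)
  bin <- array(as.integer(p >= cfg$prob_threshold), dims)
  lab <- .cpp_label_components(bin, as.integer(dims))
  sizes <- lab$sizes
  if (length(sizes) == 0L || max(sizes) < cfg$min_component_voxels) {
    m <- if (is.null(like)) binary_mask(array(0L, dims), spacing = c(1, 1, 1))
         else binary_mask(array(0L, dims), like = like)
    attr(m, "failed") <- TRUE
    attr(m, "component_sizes") <- sizes
    return(m)
  }
  keep <- which.max(sizes)  # first maximal label = raster-order tie-break
  sel <- array(as.integer(lab$labels == keep), dims)
  m <- if (is.null(like)) binary_mask(sel, spacing = c(1, 1, 1))
       else binary_mask(sel, like = like)
  attr(m, "failed") <- FALSE
  attr(m, "component_sizes") <- sizes
  m
}

#' Extract a smoothed surface mesh from a binary mask
#'
#' Runs a tetrahedral-decomposition isosurface march (a marching-cubes-family
#' algorithm) at iso-level 0.5 on the binary grid, converts vertices to mm
#' world coordinates via the mask's spacing and origin, and applies
#' volume-preserving Taubin smoothing. The mesh is watertight whenever the
#' mask does not touch the grid boundary; if it does, the (open) mesh is
#' returned with a warning.
#'
#' @param m A non-empty `sinus_mask`.
#' @param cfg A [pipeline_config()] (supplies the smoothing settings).
#' @return A `sinus_mesh` in mm coordinates.
#' @export
extract_mesh <- function(m, cfg = pipeline_config()) {
  stopifnot(inherits(m, "sinus_mask"))
  if (sum(m$voxels) == 0L) stop("cannot extract a mesh from an empty mask")
  dims <- dim(m$voxels)
  touches <- any(m$voxels[c(1, dims[1]), , ] == 1L) ||
    any(m$voxels[, c(1, dims[2]), ] == 1L) ||
    any(m$voxels[, , c(1, dims[3])] == 1L)
  if (touches)
    warning("mask touches the grid boundary; the extracted mesh is open there")
  mc <- .cpp_march_tets(as.double(m$voxels), as.integer(dims), 0.5)
  verts <- mc$vertices
  faces <- mc$faces + 1L
  sm <- cfg$smoothing
  if (sm$method == "taubin" && sm$iterations > 0 && nrow(verts) > 0)
    verts <- .cpp_smooth_taubin(verts, faces - 1L, as.integer(sm$iterations),
                                sm$lambda, sm$mu)
  world <- sweep(sweep(verts, 2, m$spacing, `*`), 2, m$origin, `+`)
  surface_mesh(world, faces)
}

#' Run the full coarse-to-fine segmentation pipeline
#'
#' Chains resampling to the working resolution, stage-1 coarse segmentation,
#' patch proposal, stage-2 fine segmentation with stitching, binarization
#' with largest-component selection, and mesh extraction. Deterministic: the
#' same input and weights give byte-identical outputs.
#'
#' @param v Input `sinus_volume` (any spacing).
#' @param coarse_net,fine_net Trained `sinus_unet`s.
#' @param cfg A [pipeline_config()].
#' @return List with `mask` (working grid), `mask_native` (input grid),
#'   `mesh` (`NULL` on failure) and `report` (patch count, component sizes,
#'   failure flag, elapsed seconds).
#' @export
run_pipeline <- function(v, coarse_net, fine_net, cfg = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  vr <- resample_isotropic(v, cfg$target_spacing)
  dims <- dim(vr$voxels)
  coarse <- coarse_segment(vr, coarse_net, cfg)
  patches <- propose_patches(coarse, cfg)
  fine <- fine_segment_and_stitch(vr, patches, fine_net, cfg)
  mask <- postprocess_prob(fine, cfg, like = vr)
  failed <- isTRUE(attr(mask, "failed"))
  mesh <- if (!failed) extract_mesh(mask, cfg) else NULL
  mask_native <- if (identical(dim(v$voxels), dims) &&
                     all(abs(v$spacing - vr$spacing) < 1e-12)) mask
                 else resample_to_grid(mask, dim(v$voxels), v$spacing, "nearest")
  report <- list(n_patches = length(patches),
                 component_sizes = attr(mask, "component_sizes"),
                 failed = failed,
                 grid = dims,
                 elapsed_s = proc.time()[["elapsed"]] - t0)
  list(mask = mask, mask_native = mask_native, mesh = mesh, report = report)
}
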