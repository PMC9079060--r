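#' Voxel-wise confusion counts between two binary masks
#'
#' @param pred,truth `sinus_mask` objects (or 3D binary arrays) on the same
#'   grid.
#' @return Named list with integer `TP`, `TN`, `FP`, `FN`;
#'   `TP + TN + FP + FN` equals the total voxel count.
#' @export
confusion_counts <- function(pred, truth) {
  p <- mask_array(pred); t_ <- mask_array(truth)
  if (!identical(dim(p), dim(t_)))
    stop("mask shapes differ: ", paste(dim(p), collapse = "x"), " vs ",
         paste(dim(t_), collapse = "x"))
  tp <- sum(p == 1L & t_ == 1L)
  fp <- sum(p == 1L & t_ == 0L)
  fn <- sum(p == 0L & t_ == 1L)
  list(TP = tp, TN = length(p) - tp - fp - fn, FP = fp, FN = fn)
}

mask_array <- function(m) {
  if (inherits(m, "sinus_mask")) return(m$voxels)
  if (is.logical(m)) return(array(as.integer(m), dim(m)))
  stopifnot(is.array(m))
  array(as.integer(m), dim(m))
}

#' Dice similarity coefficient
#'
#' `DSC = 2|X intersect Y| / (|X| + |Y|) = 2TP / (2TP + FP + FN)`; 1 means
#' complete overlap. Symmetric in its arguments. When both masks are empty
#' the value is defined as 1 (perfect agreement on absence) with a warning.
#'
#' @inheritParams confusion_counts
#' @return Value in \[0, 1\].
#' @export
dsc <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  den <- 2 * cc$TP + cc$FP + cc$FN
  if (den == 0) {
    warning("both masks are empty; DSC defined as 1")
    return(1)
  }
  2 * cc$TP / den
}

#' Intersection over union (Jaccard index)
#'
#' `IoU = |X intersect Y| / |X union Y| = TP / (TP + FP + FN)`; related to
#' the Dice coefficient by `DSC = 2 IoU / (1 + IoU)`. Both-empty input is
#' defined as 1 with a warning, as for [dsc()].
#'
#' @inheritParams confusion_counts
#' @return Value in \[0, 1\].
#' @export
iou <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  den <- cc$TP + cc$FP + cc$FN
  if (den == 0) {
    warning("both masks are empty; IoU defined as 1")
    return(1)
  }
  cc$TP / den
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Surface distance robust to a small subset of outliers: the directed
#' closest-point distance sets of both directions (a to b and b to a) are
#' pooled and the 95th percentile of the pooled set is taken (linear
#' interpolation between order statistics), making the value symmetric. For
#' masks, the compared surfaces are the boundary voxels (foreground voxels
#' with a background 6-neighbour), scaled to mm by the voxel spacing; for
#' meshes, the vertex sets are compared. Identical inputs give 0.
#'
#' @param a,b Two `sinus_mask`s on grids of equal spacing, or two
#'   `sinus_mesh`es; both non-empty.
#' @param spacing Voxel spacing (mm), only needed when masks are passed as
#'   plain arrays.
#' @param percentile Order of the percentile (default 95).
#' @return Distance in mm.
#' @export
hd95 <- function(a, b, spacing = NULL, percentile = 95) {
  pa <- surface_points(a, spacing)
  pb <- surface_points(b, spacing)
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    stop("hd95 requires two non-empty inputs")
  d <- c(.cpp_closest_point_dists(pa, pb), .cpp_closest_point_dists(pb, pa))
  unname(quantile(d, percentile / 100, type = 7))
}

surface_points <- function(x, spacing = NULL) {
  if (inherits(x, "sinus_mesh")) return(x$vertices)
  if (inherits(x, "sinus_mask")) {
    spacing <- x$spacing
    origin <- x$origin
    arr <- x$voxels
  } else {
    stopifnot(is.array(x))
    if (is.null(spacing)) stop("spacing needed for plain-array masks")
    spacing <- check_len3(spacing)
    origin <- c(0, 0, 0)
    arr <- array(as.integer(x), dim(x))
  }
  b <- .cpp_boundary_voxels(arr, as.integer(dim(arr)))
  sweep(sweep(b, 2, spacing, `*`), 2, origin, `+`)
}

#' RMS surface distance (mm)
#'
#' Root mean square of closest-point distances between two surfaces,
#' `RMS = sqrt(mean(x_i^2))` with `x_i` the distance from each vertex of one
#' mesh to the closest point on the other mesh's triangle surface
#' (point-to-triangle, not vertex-to-vertex). The two directed RMS values
#' are averaged so the result is order-independent. 0 means a perfect match.
#'
#' @param a,b Two non-empty `sinus_mesh` objects.
#' @return Distance in mm.
#' @export
rms_distance <- function(a, b) {
  stopifnot(inherits(a, "sinus_mesh"), inherits(b, "sinus_mesh"))
  if (nrow(a$faces) == 0L || nrow(b$faces) == 0L)
    stop("rms_distance requires two non-empty meshes")
  dab <- .cpp_point_mesh_dists(a$vertices, b$vertices, b$faces - 1L)
  dba <- .cpp_point_mesh_dists(b$vertices, a$vertices, a$faces - 1L)
  (rms_of(dab) + rms_of(dba)) / 2
}

rms_of <- function(x) sqrt(mean(x^2))

#' Full metrics report for one prediction/truth pair
#'
#' Confusion counts plus DSC, IoU, 95% Hausdorff distance and (when meshes
#' are supplied) the RMS surface distance.
#'
#' @param pred,truth `sinus_mask` objects on the same geometry.
#' @param pred_mesh,truth_mesh Optional `sinus_mesh` pair for the RMS metric
#'   (and mesh-based HD if preferred downstream).
#' @return A `metrics_report` list: `TP`, `TN`, `FP`, `FN`, `dsc`, `iou`,
#'   `hd95_mm`, `rms_mm` (`NA` without meshes).
#' @export
evaluate_pair <- function(pred, truth, pred_mesh = NULL, truth_mesh = NULL) {
  stopifnot(inherits(pred, "sinus_mask"), inherits(truth, "sinus_mask"))
  if (!same_geometry(pred, truth)) stop("pred and truth geometries differ")
  cc <- confusion_counts(pred, truth)
  both_empty <- (cc$TP + cc$FP + cc$FN) == 0
  d <- if (both_empty) 1 else 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN)
  j <- if (both_empty) 1 else cc$TP / (cc$TP + cc$FP + cc$FN)
  h <- if (sum(pred$voxels) > 0 && sum(truth$voxels) > 0) hd95(pred, truth) else NA_real_
  r <- if (!is.null(pred_mesh) && !is.null(truth_mesh))
    rms_distance(pred_mesh, truth_mesh) else NA_real_
  structure(list(TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
                 dsc = d, iou = j, hd95_mm = h, rms_mm = r,
                 both_empty = both_empty),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> DSC %.4f | IoU %.4f | HD95 %s mm | RMS %s mm\n",
              x$dsc, x$iou, format(x$hd95_mm, digits = 4),
              format(x$rms_mm, digits = 4)))
  invisible(x)
}

#' Batch evaluation with descriptive statistics
#'
#' Evaluates a list of prediction/truth pairs and summarizes each metric by
#' mean, SD, min and max, the descriptive layout conventionally reported for
#' segmentation test sets.
#'
#' @param pairs List of `list(pred = , truth = , pred_mesh = , truth_mesh = )`
#'   entries (mesh entries optional).
#' @return List with `per_case` (data.frame of per-case metrics) and
#'   `summary` (data.frame: metric, mean, sd, min, max).
#' @export
evaluate_batch <- function(pairs) {
  reports <- lapply(pairs, function(p)
    evaluate_pair(p$pred, p$truth, p$pred_mesh %||% NULL, p$truth_mesh %||% NULL))
  per_case <- data.frame(
    case = seq_along(reports),
    dsc = vapply(reports, `[[`, numeric(1), "dsc"),
    iou = vapply(reports, `[[`, numeric(1), "iou"),
    hd95_mm = vapply(reports, `[[`, numeric(1), "hd95_mm"),
    rms_mm = vapply(reports, `[[`, numeric(1), "rms_mm"))
  summarize <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(mean = NA, sd = NA, min = NA, max = NA))
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
      min = min(v), max = max(v))
  }
  sm <- t(vapply(per_case[c("dsc", "iou", "hd95_mm", "rms_mm")], summarize,
                 numeric(4)))
  summary <- data.frame(metric = rownames(sm), sm, row.names = NULL)
  list(per_case = per_case, summary = summary)
}
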