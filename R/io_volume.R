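#' Read a 3D volume from NIfTI or a DICOM series
#'
#' Reads a scan into a [volume()]. NIfTI geometry is taken from the header
#' (pixdim and the qform/sform translation); DICOM series are read slice by
#' slice, sorted along the slice normal, and normalized to the package's
#' canonical axis convention (axis-aligned orientation cosines are applied;
#' oblique series are rejected).
#'
#' @param path A NIfTI file or a directory of DICOM slices.
#' @param format `"auto"` (directory implies `dicom_dir`), `"nifti"` or
#'   `"dicom_dir"`.
#' @return A `sinus_volume`.
#' @seealso [write_volume()], [resample_isotropic()]
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "auto") format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (format == "dicom_dir") return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI image, got ",
                                   length(dim(arr)), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot - diag(sp))) > 1e-4 * max(sp))
    warning("NIfTI orientation is not the canonical positive-diagonal form; ",
            "voxel order is taken as stored")
  volume(array(as.double(arr), dim(arr)), spacing = sp, origin = xf[1:3, 4])
}

#' Write a volume or mask to NIfTI
#'
#' Volumes are written as float64 so that a write/read round trip reproduces
#' the voxel data bit for bit; masks are written as uint8. Spacing goes to
#' pixdim and the origin to the sform/qform translation.
#'
#' @param v A `sinus_volume` or `sinus_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, c("sinus_volume", "sinus_mask")))
  dt <- if (inherits(v, "sinus_mask")) "uint8" else "double"
  img <- RNifti::asNifti(v$voxels * 1.0)
  RNifti::pixdim(img) <- v$spacing
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname read_volume
#' @details `read_mask()` reads a NIfTI file and validates that it is binary.
#' @export
read_mask <- function(path) {
  v <- read_volume(path, format = "nifti")
  binary_mask(array(as.integer(round(v$voxels)), dim(v$voxels)),
              spacing = v$spacing, origin = v$origin)
}

#' Resample a volume to isotropic voxels
#'
#' Resamples onto an isotropic grid of `target_spacing` mm using trilinear
#' interpolation for intensities or nearest-neighbour for masks (which keeps
#' masks binary). The output shape per axis is
#' `max(1, round(shape * spacing / target_spacing))` and voxel centres are
#' aligned so the physical field of view is preserved to within one voxel.
#'
#' @param v A `sinus_volume` or `sinus_mask`.
#' @param target_spacing Positive isotropic voxel size in mm.
#' @param method `"linear"` (default for volumes) or `"nearest"` (always used
#'   for masks).
#' @return Object of the same class as `v` on the new grid.
#' @export
resample_isotropic <- function(v, target_spacing, method = NULL) {
  stopifnot(inherits(v, c("sinus_volume", "sinus_mask")))
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0)
    stop("target_spacing must be a single positive number")
  is_mask <- inherits(v, "sinus_mask")
  if (is.null(method)) method <- if (is_mask) "nearest" else "linear"
  if (is_mask) method <- "nearest"
  in_dim <- dim(v$voxels)
  if (all(abs(v$spacing - target_spacing) < 1e-12)) return(v)
  out_dim <- pmax(1L, as.integer(round(in_dim * v$spacing / target_spacing)))
  out <- resample_to_grid(v, out_dim, rep(target_spacing, 3), method)
  out
}

# Resample onto out_dim voxels whose grid is centre-aligned with the input
# field of view: both grids share the same physical centre.
resample_to_grid <- function(v, out_dim, out_spacing, method) {
  in_dim <- dim(v$voxels)
  scale <- out_spacing / v$spacing
  # centre alignment in index space: u = scale * (i - (nout-1)/2) + (nin-1)/2
  A <- diag(scale)
  t <- (in_dim - 1) / 2 - scale * (out_dim - 1) / 2
  fill <- if (inherits(v, "sinus_mask")) 0 else v$voxels[1]
  arr <- .cpp_warp_affine(as.double(v$voxels), as.integer(in_dim),
                          as.integer(out_dim), A, t, NULL, method, fill = fill)
  new_origin <- v$origin + v$spacing * t
  if (inherits(v, "sinus_mask"))
    binary_mask(array(as.integer(round(arr)), out_dim),
                spacing = out_spacing, origin = new_origin)
  else volume(array(arr, out_dim), spacing = out_spacing, origin = new_origin)
}
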