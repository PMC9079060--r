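#' 3D intensity volumes and binary masks
#'
#' A `sinus_volume` is a 3D grid of intensities in (approximate) Hounsfield
#' units together with its voxel geometry: per-axis spacing in mm/voxel and
#' the world position (mm) of the centre of voxel `[1, 1, 1]`. Indexing is
#' 0-based internally: the centre of voxel with 0-based index `i` lies at
#' `origin + i * spacing`. A `sinus_mask` shares the same geometry and holds
#' voxel values that are exactly 0 or 1.
#'
#' @param voxels 3D numeric array. For masks, values must be exactly 0 or 1
#'   (logical arrays are accepted and coerced).
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length-3, mm; world coordinates of the first voxel
#'   centre. Defaults to `c(0, 0, 0)`.
#' @return `volume()` returns a `sinus_volume`; `binary_mask()` returns a
#'   `sinus_mask`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' m <- binary_mask(array(0L, c(4, 4, 4)), like = v)
#' @export
volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- check_grid(voxels)
  if (!all(is.finite(voxels))) stop("volume intensities must be finite")
  structure(list(voxels = voxels,
                 spacing = check_len3(spacing, positive = TRUE),
                 origin = check_len3(origin)),
            class = "sinus_volume")
}

#' @rdname volume
#' @param like A `sinus_volume` or `sinus_mask` whose geometry (spacing,
#'   origin) the mask annotates; alternatively pass `spacing`/`origin`.
#' @export
binary_mask <- function(voxels, like = NULL, spacing = NULL, origin = NULL) {
  voxels <- check_grid(voxels)
  if (is.logical(voxels)) voxels <- array(as.integer(voxels), dim(voxels))
  if (!all(voxels %in% c(0L, 1L))) stop("mask values must be exactly 0 or 1")
  voxels <- array(as.integer(voxels), dim(voxels))
  if (!is.null(like)) {
    stopifnot(inherits(like, c("sinus_volume", "sinus_mask")))
    if (!identical(dim(voxels), dim(like$voxels)))
      stop("mask shape ", paste(dim(voxels), collapse = "x"),
           " does not match the annotated volume shape ",
           paste(dim(like$voxels), collapse = "x"))
    spacing <- like$spacing
    origin <- like$origin
  }
  if (is.null(spacing)) stop("provide `like` or `spacing`")
  if (is.null(origin)) origin <- c(0, 0, 0)
  structure(list(voxels = voxels,
                 spacing = check_len3(spacing, positive = TRUE),
                 origin = check_len3(origin)),
            class = "sinus_mask")
}

check_grid <- function(voxels) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("each grid dimension must be >= 1")
  voxels
}

check_len3 <- function(x, positive = FALSE) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L || !all(is.finite(x))) stop("expected 3 finite values")
  if (positive && any(x <= 0)) stop("spacing components must be > 0")
  x
}

#' @export
print.sinus_volume <- function(x, ...) {
  cat("<sinus_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, HU range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.sinus_mask <- function(x, ...) {
  cat("<sinus_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", sum(x$voxels), " foreground, spacing ",
      paste(signif(x$spacing, 4), collapse = "/"), " mm\n", sep = "")
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Triangle surface meshes
#'
#' A `sinus_mesh` stores vertices in mm world coordinates and 1-based
#' vertex-index triples. Degenerate (zero-area) faces are rejected.
#'
#' @param vertices n x 3 numeric matrix of points (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `sinus_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (nrow(faces) > 0L) {
    a <- vertices[faces[, 1], , drop = FALSE]
    n <- vec_cross(vertices[faces[, 2], , drop = FALSE] - a,
                   vertices[faces[, 3], , drop = FALSE] - a)
    if (any(rowSums(n^2) == 0)) stop("mesh contains degenerate (zero-area) faces")
  }
  structure(list(vertices = vertices, faces = faces), class = "sinus_mesh")
}

#' @export
print.sinus_mesh <- function(x, ...) {
  cat("<sinus_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces\n", sep = "")
  invisible(x)
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume via the divergence theorem (sum of signed tetrahedra against
#' the origin). Meaningful for closed meshes with consistent outward winding;
#' the absolute value is returned.
#'
#' @param mesh A `sinus_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "sinus_mesh"))
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  abs(sum(rowSums(a * vec_cross(b, c_))) / 6)
}
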