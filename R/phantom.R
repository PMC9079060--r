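#' Specification of a synthetic sinus phantom
#'
#' Describes a CBCT-like phantom: an air-filled cavity shaped as a rotated
#' superellipsoid (a cheap stand-in for the pyramidal sinus shape), surrounded
#' by a bone shell inside uniform soft tissue, with an optional mucosal lining
#' of given thickness on the cavity wall and an optional ostium-like channel
#' that connects the cavity to a second, smaller "nasal" air cavity. The
#' ground-truth mask covers the air interior of the main cavity only: the
#' lining and the channel beyond its mouth are excluded, mimicking the
#' convention of cutting the segmentation at the early start of the ostium.
#'
#' Default HU levels are standard CT values (air -1000, soft tissue +40,
#' mucosa +30, bone +1000), chosen so the conventional air threshold window
#' (-1024 to -200 HU) isolates air. Gaussian noise of `noise_sd` HU is added
#' last.
#'
#' @param grid_shape Integer length-3 grid size (voxels).
#' @param spacing Isotropic voxel size in mm (single number or length 3).
#' @param semi_axes Cavity superellipsoid semi-axes (mm).
#' @param center Cavity centre (mm, world coordinates); default grid centre.
#' @param rotation Euler angles (degrees, applied z-y-x) of the cavity.
#' @param exponent Superellipsoid exponent (2 = ellipsoid; larger = boxier).
#' @param thickening_mm Mucosal lining thickness in mm (0 = none). Clinically,
#'   shallow thickening is > 2 mm and moderate > 4 mm.
#' @param bone_shell_mm Bone shell thickness in mm.
#' @param ostium Either `NULL` (no channel) or a list with elements
#'   `radius_mm`, `direction` (length-3), and `nasal_semi_axes_mm` for the
#'   second cavity the channel drains into.
#' @param hu_levels Named list with `air`, `soft_tissue`, `bone`, `mucosa`.
#' @param noise_sd Additive Gaussian noise standard deviation (HU).
#' @param seed Integer seed making the phantom fully reproducible.
#' @return A `phantom_spec` list.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing = 0.4,
                         semi_axes = c(9, 7.5, 8),
                         center = NULL,
                         rotation = c(0, 0, 0),
                         exponent = 2,
                         thickening_mm = 0,
                         bone_shell_mm = 1.2,
                         ostium = NULL,
                         hu_levels = list(air = -1000, soft_tissue = 40,
                                          bone = 1000, mucosa = 30),
                         noise_sd = 40,
                         seed = 1L) {
  grid_shape <- as.integer(check_len3(grid_shape))
  spacing <- check_len3(spacing, positive = TRUE)
  semi_axes <- check_len3(semi_axes, positive = TRUE)
  if (is.null(center)) center <- (grid_shape - 1) / 2 * spacing
  center <- check_len3(center)
  if (thickening_mm < 0) stop("thickening_mm must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (bone_shell_mm <= 0) stop("bone_shell_mm must be > 0")
  if (exponent <= 0) stop("exponent must be > 0")
  stopifnot(all(c("air", "soft_tissue", "bone", "mucosa") %in% names(hu_levels)))
  extent <- grid_shape * spacing
  reach <- max(semi_axes) + bone_shell_mm
  if (any(center - reach < 0) || any(center + reach > extent))
    stop("cavity (with bone shell) does not fit inside the grid")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 semi_axes = semi_axes, center = center, rotation = rotation,
                 exponent = exponent, thickening_mm = thickening_mm,
                 bone_shell_mm = bone_shell_mm, ostium = ostium,
                 hu_levels = hu_levels, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

euler_matrix <- function(deg) {
  r <- deg * pi / 180
  cz <- cos(r[1]); sz <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cx <- cos(r[3]); sx <- sin(r[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

# Superellipsoid inside-ness: implicit value <= 1 means inside the surface
# with the given semi-axes; vectorized over an n x 3 matrix of local mm
# coordinates (already rotated into the cavity frame).
superellipsoid_value <- function(local_mm, semi_axes, exponent) {
  (abs(local_mm[, 1]) / semi_axes[1])^exponent +
    (abs(local_mm[, 2]) / semi_axes[2])^exponent +
    (abs(local_mm[, 3]) / semi_axes[3])^exponent
}

#' Generate a synthetic CBCT phantom with its ground-truth mask
#'
#' Rasterizes the phantom described by a [phantom_spec()]: voxels inside the
#' (shrunken-by-lining) cavity get the air HU level, the lining gets the
#' mucosa level, the bone shell the bone level and everything else soft
#' tissue. If an ostium is specified, an air channel and the nasal cavity are
#' carved through the shell, but only the main cavity interior enters the
#' ground truth. Gaussian noise is added last; the entire construction is
#' deterministic given `spec$seed`.
#'
#' @param spec A `phantom_spec`.
#' @return A list of class `phantom_sample` with elements `volume`
#'   (`sinus_volume`), `truth` (`sinus_mask`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1)))
  world <- sweep(idx, 2, spec$spacing, `*`)
  local <- sweep(world, 2, spec$center, `-`) %*% euler_matrix(spec$rotation)

  air_axes <- spec$semi_axes - spec$thickening_mm
  if (any(air_axes <= spec$spacing))
    stop("mucosal thickening leaves no air cavity")
  inner <- superellipsoid_value(local, air_axes, spec$exponent) <= 1
  cavity <- superellipsoid_value(local, spec$semi_axes, spec$exponent) <= 1
  shell <- superellipsoid_value(local, spec$semi_axes + spec$bone_shell_mm,
                                spec$exponent) <= 1

  hu <- rep(spec$hu_levels$soft_tissue, nrow(idx))
  hu[shell] <- spec$hu_levels$bone
  hu[cavity] <- spec$hu_levels$mucosa   # lining (overwritten by air inside)
  hu[inner] <- spec$hu_levels$air
  truth <- inner

  if (!is.null(spec$ostium)) {
    os <- spec$ostium
    dir <- os$direction / sqrt(sum(os$direction^2))
    # channel from the cavity centre out past the bone shell, then a small
    # "nasal" cavity beyond its far end
    len <- max(spec$semi_axes) + spec$bone_shell_mm + os$radius_mm
    rel <- sweep(world, 2, spec$center, `-`)
    along <- as.vector(rel %*% dir)
    radial2 <- rowSums(rel^2) - along^2
    channel <- along >= 0 & along <= len & radial2 <= os$radius_mm^2
    nasal_center <- spec$center + dir * (len + max(os$nasal_semi_axes_mm) * 0.8)
    nasal_local <- sweep(world, 2, nasal_center, `-`)
    nasal <- superellipsoid_value(nasal_local, check_len3(os$nasal_semi_axes_mm),
                                  2) <= 1
    hu[channel | nasal] <- spec$hu_levels$air
    # truth keeps only the main cavity: the channel past its mouth (outside
    # the cavity surface) and the nasal cavity stay excluded
  }

  if (spec$noise_sd > 0) {
    hu <- hu + with_seed(spec$seed, rnorm(length(hu), sd = spec$noise_sd))
  }
  vol <- volume(array(hu, d), spacing = spec$spacing, origin = c(0, 0, 0))
  msk <- binary_mask(array(as.integer(truth), d), like = vol)
  structure(list(volume = vol, truth = msk, spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat("<phantom_sample> ", paste(dim(x$volume$voxels), collapse = " x "),
      " voxels, truth ", sum(x$truth$voxels), " voxels\n", sep = "")
  invisible(x)
}

# run code under a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a well-separated child seed from a base seed (kept below 2^31)
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 1299721) %% 2147483647
}

#' Generate a reproducible phantom dataset with optional train/val/test split
#'
#' Draws `n` phantoms from `base_spec` with per-sample jitter of the cavity
#' geometry: semi-axes scaled uniformly within `size_range`, rotation angles
#' uniform within `±rotation_deg`, and mucosal thickening present in
#' `thickening_fraction` of the samples with thickness uniform in
#' `thickening_range_mm`. Each sample gets an independent noise seed derived
#' from `seed`, so the whole dataset is reproducible from one integer.
#'
#' @param n Number of phantoms (>= 1).
#' @param base_spec The `phantom_spec` the jitter perturbs.
#' @param jitter List with any of `size_range` (default `c(0.85, 1.15)`),
#'   `rotation_deg` (default 15), `thickening_fraction` (default 0.5),
#'   `thickening_range_mm` (default `c(2, 4)`).
#' @param seed Integer seed.
#' @param split Optional numeric vector of fractions summing to 1, e.g.
#'   `c(train = 0.6, val = 0.15, test = 0.25)`; samples are partitioned
#'   disjointly in order of the shuffled sample list.
#' @return A list of `phantom_sample` (unsplit), or a named list of such
#'   lists when `split` is given.
#' @export
generate_dataset <- function(n, base_spec = phantom_spec(), jitter = list(),
                             seed = 1L, split = NULL) {
  if (n < 1) stop("n must be >= 1")
  jit <- modifyList(list(size_range = c(0.85, 1.15), rotation_deg = 15,
                         thickening_fraction = 0.5,
                         thickening_range_mm = c(2, 4)), jitter)
  draws <- with_seed(derive_seed(seed, 1), {
    lapply(seq_len(n), function(i) {
      list(size = runif(1, jit$size_range[1], jit$size_range[2]),
           rot = runif(3, -jit$rotation_deg, jit$rotation_deg),
           thick = if (runif(1) < jit$thickening_fraction)
             runif(1, jit$thickening_range_mm[1], jit$thickening_range_mm[2])
           else 0)
    })
  })
  samples <- lapply(seq_len(n), function(i) {
    dr <- draws[[i]]
    sp <- base_spec
    sp$semi_axes <- base_spec$semi_axes * dr$size
    sp$rotation <- base_spec$rotation + dr$rot
    sp$thickening_mm <- dr$thick
    sp$seed <- as.integer(derive_seed(seed, 100 + i))
    extent <- sp$grid_shape * sp$spacing
    reach <- max(sp$semi_axes) + sp$bone_shell_mm
    if (any(sp$center - reach < 0) || any(sp$center + reach > extent))
      stop("jittered cavity of sample ", i, " does not fit inside the grid")
    generate_phantom(sp)
  })
  if (is.null(split)) return(samples)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  sizes <- diff(round(cumsum(c(0, split)) * n))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  parts <- lapply(seq_along(split), function(k)
    if (sizes[k] == 0) list() else samples[starts[k]:ends[k]])
  names(parts) <- names(split) %||% paste0("part", seq_along(split))
  parts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold a volume to an air mask
#'
#' Marks every voxel whose intensity lies in the closed interval
#' `[lo, hi]` — the conventional air window used when seeding a sinus
#' segmentation from CT/CBCT intensities.
#'
#' @param v A `sinus_volume`.
#' @param lo,hi Window bounds in HU, inclusive on both ends; `lo < hi`.
#' @return A `sinus_mask` on the same grid.
#' @export
threshold_air_mask <- function(v, lo = -1024, hi = -200) {
  stopifnot(inherits(v, "sinus_volume"))
  if (!(lo < hi)) stop("lo must be < hi")
  binary_mask(v$voxels >= lo & v$voxels <= hi, like = v)
}
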