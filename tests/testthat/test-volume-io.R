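test_that("NIfTI write/read round trip preserves voxels and geometry", {
  set.seed(1)
  v <- volume(array(rnorm(5 * 6 * 7, sd = 300), c(5, 6, 7)),
              spacing = c(0.3, 0.4, 0.5), origin = c(1, -2, 3))
  path <- tempfile(fileext = ".nii")
  write_volume(v, path)
  r <- read_volume(path)
  expect_identical(r$voxels, v$voxels)          # float64 on disk: bit-exact
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-4)

  m <- binary_mask(array(as.integer(v$voxels > 0), dim(v$voxels)), like = v)
  mpath <- tempfile(fileext = ".nii")
  write_volume(m, mpath)
  rm_ <- read_mask(mpath)
  expect_identical(rm_$voxels, m$voxels)
  expect_error(read_volume(tempfile(fileext = ".nii")), "exist")
})

test_that("volume and mask constructors enforce their invariants", {
  expect_error(volume(array(c(1, NA), c(2, 1, 1)), spacing = 1), "finite")
  expect_error(volume(matrix(0, 2, 2), spacing = 1), "3D")
  expect_error(volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "> 0")
  v <- volume(array(0, c(3, 3, 3)), spacing = 1)
  expect_error(binary_mask(array(2L, c(3, 3, 3)), like = v), "exactly 0 or 1")
  expect_error(binary_mask(array(0L, c(2, 3, 3)), like = v), "shape")
  m <- binary_mask(array(TRUE, c(3, 3, 3)), like = v)
  expect_identical(unique(as.vector(m$voxels)), 1L)
})

test_that("isotropic resampling honours shape arithmetic and identities", {
  v <- volume(array(rnorm(64^3, sd = 100), c(64, 64, 64)), spacing = 0.5)
  out <- resample_isotropic(v, 1.0)
  expect_identical(dim(out$voxels), c(32L, 32L, 32L))
  expect_equal(out$spacing, rep(1, 3))

  # already at target: untouched
  same <- resample_isotropic(v, 0.5)
  expect_identical(same$voxels, v$voxels)

  # constant volume stays constant under interpolation
  cv <- volume(array(42, c(16, 16, 16)), spacing = 0.5)
  expect_true(all(resample_isotropic(cv, 0.7)$voxels == 42))

  expect_error(resample_isotropic(v, -1), "positive")

  # physical extent preserved within one target voxel per axis
  v2 <- volume(array(0, c(20, 30, 17)), spacing = c(0.31, 0.45, 0.8))
  r2 <- resample_isotropic(v2, 0.5)
  extent_in <- dim(v2$voxels) * v2$spacing
  extent_out <- dim(r2$voxels) * r2$spacing
  expect_true(all(abs(extent_in - extent_out) < 0.5))
})

test_that("resampling twice to the same target equals resampling once", {
  # smooth field so interpolation error is the only difference
  g <- seq(0, 2 * pi, length.out = 24)
  arr <- outer(outer(sin(g), cos(g)), sin(2 * g)) * 100
  v <- volume(arr, spacing = 0.55)
  r1 <- resample_isotropic(v, 0.8)
  r2 <- resample_isotropic(r1, 0.8)
  expect_identical(r2$voxels, r1$voxels)
  # masks stay binary through nearest-neighbour resampling
  m <- binary_mask(array(as.integer(arr > 0), dim(arr)), like = v)
  rm_ <- resample_isotropic(m, 0.8)
  expect_true(all(rm_$voxels %in% c(0L, 1L)))
})

test_that("synthetic DICOM series round trips through the reader", {
  spec <- small_phantom_spec(seed = 2, noise_sd = 0, grid = 16L)
  ph <- generate_phantom(spec)
  dir <- file.path(tempdir(), "dcm_rt")
  unlink(dir, recursive = TRUE)
  write_dicom_series(ph$volume, dir)
  expect_length(list.files(dir), 16L)
  r <- read_volume(dir, format = "dicom_dir")
  expect_identical(dim(r$voxels), dim(ph$volume$voxels))
  expect_equal(r$voxels, ph$volume$voxels)      # integer HU: exact after rescale
  expect_equal(r$spacing, ph$volume$spacing, tolerance = 1e-6)
  expect_equal(r$origin, ph$volume$origin, tolerance = 1e-6)
})

test_that("a 20-slice series at 0.3 mm yields depth 20 and the slice gap", {
  arr <- array(round(rnorm(8 * 8 * 20, sd = 200)), c(8, 8, 20))
  v <- volume(arr, spacing = c(0.3, 0.3, 0.45), origin = c(0, 0, 5))
  dir <- file.path(tempdir(), "dcm_gap")
  unlink(dir, recursive = TRUE)
  write_dicom_series(v, dir)
  r <- read_volume(dir)
  expect_identical(dim(r$voxels)[3], 20L)
  expect_equal(r$spacing, c(0.3, 0.3, 0.45), tolerance = 1e-6)
  expect_equal(r$voxels, arr)
})

test_that("a series with one rotated slice is rejected naming the attribute", {
  arr <- array(0, c(8, 8, 6))
  v <- volume(arr, spacing = 0.3)
  dir <- file.path(tempdir(), "dcm_rot")
  unlink(dir, recursive = TRUE)
  write_dicom_series(v, dir)
  f <- file.path(dir, "slice_0003.dcm")
  raw <- readBin(f, "raw", file.info(f)$size)
  # patch ImageOrientationPatient "1\0\0\0\1\0" -> a flipped row direction
  pat <- charToRaw("1\\0\\0\\0\\1\\0")
  hit <- NULL
  for (i in seq_len(length(raw) - length(pat))) {
    if (all(raw[i:(i + length(pat) - 1)] == pat)) { hit <- i; break }
  }
  expect_false(is.null(hit))
  raw[hit:(hit + length(pat) - 1)] <- charToRaw("0\\1\\0\\1\\0\\0")
  writeBin(raw, f)
  expect_error(read_volume(dir), "ImageOrientationPatient")
})

test_that("an independent DICOM implementation reads our series identically", {
  # cross-check the hand-rolled writer against pydicom
  arr <- array(round(rnorm(6 * 5 * 4, sd = 100)), c(6, 5, 4))
  v <- volume(arr, spacing = c(0.25, 0.3, 0.5), origin = c(1, 2, 3))
  dir <- file.path(tempdir(), "dcm_py")
  unlink(dir, recursive = TRUE)
  write_dicom_series(v, dir)
  script <- paste(
    "import pydicom, glob, sys",
    sprintf("fs = sorted(glob.glob('%s/*.dcm'))", dir),
    "ds = pydicom.dcmread(fs[0])",
    "px = ds.pixel_array",
    "print(px.shape[0], px.shape[1], len(fs))",
    "print(float(ds.PixelSpacing[0]), float(ds.PixelSpacing[1]))",
    "print(' '.join(str(int(x)) for x in px.flatten()))",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  dims <- as.integer(strsplit(out[1], " ")[[1]])
  expect_identical(dims, c(5L, 6L, 4L))                 # rows, cols, slices
  expect_equal(as.numeric(strsplit(out[2], " ")[[1]]), c(0.3, 0.25))
  px <- as.numeric(strsplit(out[3], " ")[[1]])
  # pydicom returns row-major rows x cols; our slice 1 transposed
  expect_equal(matrix(px, nrow = 5, byrow = TRUE), t(arr[, , 1]))
})

test_that("STL binary and ascii round trips preserve geometry", {
  m <- cube_mesh()
  fb <- tempfile(fileext = ".stl")
  fa <- tempfile(fileext = ".stl")
  write_stl(m, fb, mode = "binary")
  write_stl(m, fa, mode = "ascii")
  rb <- read_stl(fb)
  ra <- read_stl(fa)
  expect_identical(nrow(rb$faces), 12L)
  expect_identical(nrow(ra$faces), 12L)
  # same vertex sets within float32 tolerance
  sort_rows <- function(v) v[do.call(order, as.data.frame(v)), ]
  expect_equal(sort_rows(rb$vertices), sort_rows(m$vertices),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sort_rows(ra$vertices), sort_rows(rb$vertices),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(write_stl(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                         tempfile()), "empty")
})

test_that("watertightness survives an STL round trip", {
  spec <- small_phantom_spec(seed = 3, noise_sd = 0, grid = 24L)
  ph <- generate_phantom(spec)
  mesh <- extract_mesh(ph$truth, pipeline_config(smoothing = list(method = "none")))
  f <- tempfile(fileext = ".stl")
  write_stl(mesh, f)
  r <- read_stl(f)
  expect_identical(nrow(r$faces), nrow(mesh$faces))
  counts <- edge_use_counts(r)
  expect_true(all(counts == 2))
})

test_that("an independent mesh library accepts our binary STL", {
  mesh <- cube_mesh(2)
  f <- tempfile(fileext = ".stl")
  write_stl(mesh, f)
  script <- paste(
    "import trimesh",
    sprintf("m = trimesh.load('%s')", f),
    "print(len(m.faces), m.is_watertight, round(float(m.volume), 6))",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  parts <- strsplit(out[length(out)], " ")[[1]]
  expect_identical(parts[1], "12")
  expect_identical(parts[2], "True")
  expect_equal(as.numeric(parts[3]), 8)
})
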