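# Minimal DICOM support: uncompressed single-frame CT image slices in the
# Explicit VR Little Endian transfer syntax (the form in which CBCT scans are
# exported by acquisition consoles and by this package's own series writer).
# No installed R package reads DICOM, so the byte-level parsing lives here;
# scope is deliberately narrow and anything else is rejected loudly.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, read_dicom_slice)

  ori <- slices[[1]]$orientation
  for (s in slices) {
    if (max(abs(s$orientation - ori)) > 1e-4)
      stop("inconsistent DICOM series: ImageOrientationPatient differs ",
           "between slices")
    if (!identical(dim(s$pixels), dim(slices[[1]]$pixels)))
      stop("inconsistent DICOM series: Rows/Columns differ between slices")
    if (max(abs(s$pixel_spacing - slices[[1]]$pixel_spacing)) > 1e-6)
      stop("inconsistent DICOM series: PixelSpacing differs between slices")
  }
  row_dir <- ori[1:3]   # direction of increasing column index
  col_dir <- ori[4:6]   # direction of increasing row index
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  pos <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  if (length(slices) > 1L) {
    gaps <- diff(pos)
    if (any(gaps <= 0) || (max(gaps) - min(gaps)) > 1e-3 * mean(gaps))
      stop("inconsistent DICOM series: non-uniform slice positions ",
           "(ImagePositionPatient)")
    gap <- mean(gaps)
  } else gap <- 1
  axis_of <- function(d) {
    a <- which.max(abs(d))
    if (abs(abs(d[a]) - 1) > 1e-3 || sum(abs(d)) - abs(d[a]) > 1e-3)
      stop("oblique DICOM series are not supported: ",
           "ImageOrientationPatient is not axis-aligned")
    c(axis = a, sign = sign(d[a]))
  }
  ar <- axis_of(row_dir); ac <- axis_of(col_dir); an <- axis_of(normal)
  if (length(unique(c(ar[1], ac[1], an[1]))) != 3L)
    stop("degenerate ImageOrientationPatient")

  nc <- ncol(slices[[1]]$pixels)  # columns  (index i, along row_dir)
  nr <- nrow(slices[[1]]$pixels)  # rows     (index j, along col_dir)
  ns <- length(slices)
  # stack as [column, row, slice] then permute to canonical x, y, z
  stack <- array(0, c(nc, nr, ns))
  for (k in seq_len(ns)) stack[, , k] <- t(slices[[k]]$pixels)
  axes <- c(ar[1], ac[1], an[1])
  signs <- c(ar[2], ac[2], an[2])
  perm <- match(1:3, axes)
  vox <- aperm(stack, perm)
  for (w in 1:3) if (signs[perm[w]] < 0)
    vox <- flip_axis(vox, w)
  sp_stack <- c(slices[[1]]$pixel_spacing[2], slices[[1]]$pixel_spacing[1], gap)
  spacing <- sp_stack[perm]
  # world coordinate of the minimal-index voxel centre along each axis
  corners <- vapply(seq_len(ns), function(k) slices[[k]]$position, numeric(3))
  all_pos <- cbind(
    slices[[1]]$position,
    slices[[1]]$position + row_dir * slices[[1]]$pixel_spacing[2] * (nc - 1),
    slices[[1]]$position + col_dir * slices[[1]]$pixel_spacing[1] * (nr - 1),
    corners)
  origin <- apply(all_pos, 1, min)
  volume(vox, spacing = spacing, origin = origin)
}

flip_axis <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  n <- length(raw)
  if (n < 140) stop("corrupt or truncated DICOM file: ", path)
  off <- 0L
  if (n > 132 && rawToChar(raw[129:132]) == "DICM") off <- 132L
  u16 <- function(i) as.integer(raw[i + 1L]) + 256L * as.integer(raw[i + 2L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  i <- off
  while (i + 8 <= n) {
    group <- u16(i); elem <- u16(i + 2L)
    vr <- rawToChar(raw[(i + 5L):(i + 6L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported DICOM encoding (expected Explicit VR little endian) in ",
           path)
    if (vr %in% long_vrs) { len <- u32(i + 8L); hdr <- 12L } else { len <- u16(i + 6L); hdr <- 8L }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported")
    val_start <- i + hdr
    if (val_start + len > n) stop("corrupt DICOM element in ", path)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, raw = raw[seq.int(val_start + 1L, length.out = len)])
    i <- val_start + len
  }
  ts <- dicom_str(tags, "0002,0010")
  if (!is.null(ts) && ts != DICOM_EXPLICIT_LE)
    stop("unsupported DICOM transfer syntax ", ts, " (only Explicit VR ",
         "little endian is supported)")
  need <- function(key, what) {
    if (is.null(tags[[key]])) stop("DICOM file ", path, " lacks ", what)
    tags[[key]]
  }
  rows <- dicom_u16(need("0028,0010", "Rows"))
  cols <- dicom_u16(need("0028,0011", "Columns"))
  bits <- dicom_u16(need("0028,0100", "BitsAllocated"))
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  signed <- !is.null(tags[["0028,0103"]]) && dicom_u16(tags[["0028,0103"]]) == 1L
  slope <- dicom_ds1(tags, "0028,1053", 1)
  inter <- dicom_ds1(tags, "0028,1052", 0)
  pos <- dicom_ds(need("0020,0032", "ImagePositionPatient"))
  ori <- dicom_ds(need("0020,0037", "ImageOrientationPatient"))
  psp <- dicom_ds(need("0028,0030", "PixelSpacing"))
  px <- need("7fe0,0010", "PixelData")
  vals <- readBin(px$raw, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
  if (length(vals) != rows * cols) stop("PixelData length mismatch in ", path)
  m <- matrix(vals * slope + inter, nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = m, position = pos, orientation = ori, pixel_spacing = psp)
}

dicom_str <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  sub(" +$", "", rawToChar(el$raw[el$raw != as.raw(0)]))
}
dicom_u16 <- function(el) readBin(el$raw, "integer", 1L, size = 2L,
                                  signed = FALSE, endian = "little")
dicom_ds <- function(el) as.numeric(strsplit(rawToChar(el$raw), "\\\\")[[1]])
dicom_ds1 <- function(tags, key, default) {
  el <- tags[[key]]
  if (is.null(el)) return(default)
  dicom_ds(el)[1]
}

#' Write a volume as a synthetic DICOM series
#'
#' Writes one Explicit-VR little-endian CT slice per z index, with identity
#' orientation, 16-bit signed pixels and a rescale of 1/0 (values are clamped
#' to the int16 range). Primarily used to exercise the DICOM reading path and
#' to export phantoms; the files carry synthetic UIDs.
#'
#' @param v A `sinus_volume`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(v, dir) {
  stopifnot(inherits(v, "sinus_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(v$voxels)
  series_uid <- dicom_uid(1)
  study_uid <- dicom_uid(2)
  for (k in seq_len(d[3])) {
    sl <- v$voxels[, , k]
    vals <- as.integer(pmin(32767, pmax(-32768, round(sl))))
    # PixelData is row-major: columns (x) fastest, as.vector(sl) already is
    pix <- writeBin(vals, raw(), size = 2L, endian = "little")
    pos <- v$origin + c(0, 0, (k - 1) * v$spacing[3])
    els <- c(
      dicom_el(0x0008, 0x0016, "UI", dicom_pad("1.2.840.10008.5.1.4.1.1.2")),
      dicom_el(0x0008, 0x0018, "UI", dicom_pad(dicom_uid(100 + k))),
      dicom_el(0x0008, 0x0060, "CS", dicom_pad("CT", " ")),
      dicom_el(0x0020, 0x000d, "UI", dicom_pad(study_uid)),
      dicom_el(0x0020, 0x000e, "UI", dicom_pad(series_uid)),
      dicom_el(0x0020, 0x0013, "IS", dicom_pad(as.character(k), " ")),
      dicom_el(0x0020, 0x0032, "DS",
               dicom_pad(paste(format(pos, trim = TRUE), collapse = "\\"), " ")),
      dicom_el(0x0020, 0x0037, "DS", dicom_pad("1\\0\\0\\0\\1\\0", " ")),
      dicom_el(0x0028, 0x0002, "US", writeBin(1L, raw(), size = 2L, endian = "little")),
      dicom_el(0x0028, 0x0004, "CS", dicom_pad("MONOCHROME2", " ")),
      dicom_el(0x0028, 0x0010, "US", writeBin(as.integer(d[2]), raw(), size = 2L, endian = "little")),
      dicom_el(0x0028, 0x0011, "US", writeBin(as.integer(d[1]), raw(), size = 2L, endian = "little")),
      dicom_el(0x0028, 0x0030, "DS",
               dicom_pad(paste(format(c(v$spacing[2], v$spacing[1]), trim = TRUE),
                               collapse = "\\"), " ")),
      dicom_el(0x0028, 0x0100, "US", writeBin(16L, raw(), size = 2L, endian = "little")),
      dicom_el(0x0028, 0x0101, "US", writeBin(16L, raw(), size = 2L, endian = "little")),
      dicom_el(0x0028, 0x0102, "US", writeBin(15L, raw(), size = 2L, endian = "little")),
      dicom_el(0x0028, 0x0103, "US", writeBin(1L, raw(), size = 2L, endian = "little")),
      dicom_el(0x0028, 0x1052, "DS", dicom_pad("0", " ")),
      dicom_el(0x0028, 0x1053, "DS", dicom_pad("1", " ")),
      dicom_el(0x7fe0, 0x0010, "OW", pix)
    )
    meta <- dicom_el(0x0002, 0x0010, "UI", dicom_pad(DICOM_EXPLICIT_LE))
    out <- c(raw(128), charToRaw("DICM"), meta, els)
    writeBin(out, file.path(dir, sprintf("slice_%04d.dcm", k)))
  }
  invisible(dir)
}

dicom_uid <- function(k) paste0("1.2.826.0.1.3680043.9999.", k)
# UI values pad with NUL (the default); string VRs pad with space
dicom_pad <- function(s, pad = NULL) {
  r <- charToRaw(s)
  if (length(r) %% 2L) r <- c(r, if (is.null(pad)) as.raw(0) else charToRaw(pad))
  r
}
dicom_el <- function(group, elem, vr, value) {
  hdr <- writeBin(as.integer(c(group, elem)), raw(), size = 2L, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, charToRaw(vr), raw(2),
      writeBin(length(value), raw(), size = 4L, endian = "little"), value)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(value), raw(), size = 2L, endian = "little"), value)
  }
}
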