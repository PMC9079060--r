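#' Write and read STL surface files
#'
#' `write_stl()` exports a [surface_mesh()] as STL, by default in the binary
#' little-endian dialect (the de-facto exchange form); `mode = "ascii"` writes
#' the text dialect. One facet is written per mesh face, with its normal
#' computed from the vertex winding; coordinates are in mm. `read_stl()` reads
#' either dialect back, welding identical vertex coordinates into a shared
#' vertex list so that watertightness is preserved through a round trip.
#'
#' @param m A `sinus_mesh` with at least one face.
#' @param path Output file.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @return `write_stl()` returns `path` invisibly; `read_stl()` returns a
#'   `sinus_mesh`.
#' @export
write_stl <- function(m, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "sinus_mesh"))
  if (nrow(m$faces) == 0L) stop("empty mesh: nothing to export")
  v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
  v2 <- m$vertices[m$faces[, 2], , drop = FALSE]
  v3 <- m$vertices[m$faces[, 3], , drop = FALSE]
  nrm <- vec_cross(v2 - v1, v3 - v1)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  nf <- nrow(m$faces)
  if (mode == "binary") {
    con <- tryCatch(file(path, "wb"), error = function(e)
      stop("cannot write STL to ", path, ": ", conditionMessage(e)))
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(nf, con, size = 4L, endian = "little")
    tri <- t(cbind(nrm, v1, v2, v3))  # 12 floats per facet, facets in columns
    for (i in seq_len(nf)) {
      writeBin(as.numeric(tri[, i]), con, size = 4L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    }
  } else {
    con <- tryCatch(file(path, "wt"), error = function(e)
      stop("cannot write STL to ", path, ": ", conditionMessage(e)))
    on.exit(close(con))
    writeLines("solid mesh", con)
    fmt <- function(p) paste(format(p, scientific = TRUE, digits = 9), collapse = " ")
    for (i in seq_len(nf)) {
      writeLines(c(paste("facet normal", fmt(nrm[i, ])),
                   "  outer loop",
                   paste("    vertex", fmt(v1[i, ])),
                   paste("    vertex", fmt(v2[i, ])),
                   paste("    vertex", fmt(v3[i, ])),
                   "  endloop",
                   "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file does not exist: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  nf <- if (sz >= 84) readBin(con, "integer", 1, size = 4L, endian = "little") else -1
  close(con)
  binary <- (sz == 84 + 50 * as.numeric(nf))
  if (binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84)
    tri <- matrix(0, nrow = 9, ncol = nf)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "numeric", 12, size = 4L, endian = "little")
      readBin(con, "raw", 2)
      tri[, i] <- vals[4:12]
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) %% 3L != 0L) stop("malformed ASCII STL: ", path)
    coords <- t(vapply(strsplit(trimws(vl), "\\s+"),
                       function(p) as.numeric(p[2:4]), numeric(3)))
    nf <- nrow(coords) / 3L
    tri <- matrix(t(coords), nrow = 9, ncol = nf)
  }
  pts <- matrix(tri, nrow = 3)                 # 3 x (3*nf), vertices in order
  key <- paste(pts[1, ], pts[2, ], pts[3, ], sep = "/")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  surface_mesh(t(pts[, uniq, drop = FALSE]),
               matrix(idx, nrow = nf, ncol = 3, byrow = TRUE))
}
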