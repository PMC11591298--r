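#' Read and write STL surface meshes
#'
#' Minimal STL support for implant and bone component surfaces. Both the
#' ASCII and the little-endian binary dialects are handled; on read the
#' format is auto-detected. Vertices are welded (exact coordinate match)
#' so round-tripped meshes keep shared topology.
#'
#' @param mesh a [trimesh()].
#' @param path file path.
#' @param binary write binary STL (default) or ASCII.
#' @param name solid name for ASCII output.
#' @return `read_stl()` returns a [trimesh()]; `write_stl()` returns
#'   `path` invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE, name = "kneebc") {
  stopifnot(inherits(mesh, "trimesh"))
  v <- mesh$vertices; f <- mesh$faces
  n_tri <- nrow(f)
  normals <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("binary stl", name)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n_tri), con, size = 4L, endian = "little")
    buf <- matrix(0, 12L, n_tri)
    for (i in seq_len(n_tri))
      buf[, i] <- c(normals[i, ], t(v[f[i, ], ]))
    for (i in seq_len(n_tri)) {
      writeBin(as.numeric(buf[, i]), con, size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    lines <- character(7L * n_tri + 2L)
    lines[1L] <- paste("solid", name)
    k <- 2L
    for (i in seq_len(n_tri)) {
      lines[k] <- sprintf("  facet normal %.9e %.9e %.9e",
                          normals[i, 1], normals[i, 2], normals[i, 3])
      lines[k + 1L] <- "    outer loop"
      for (j in 1:3)
        lines[k + 1L + j] <- sprintf("      vertex %.9e %.9e %.9e",
                                     v[f[i, j], 1], v[f[i, j], 2], v[f[i, j], 3])
      lines[k + 5L] <- "    endloop"
      lines[k + 6L] <- "  endfacet"
      k <- k + 7L
    }
    lines[k] <- paste("endsolid", name)
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 512L)
  printable <- head >= as.raw(0x09) & head <= as.raw(0x7e)
  txt <- rawToChar(head[printable])
  is_ascii <- all(printable | head == as.raw(0)) &&
    grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  weld_triangles(nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  tri <- matrix(NA_real_, 3L * n_tri, 3L)
  for (i in seq_len(n_tri)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    tri[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
  }
  weld_triangles(tri)
}

# Rebuild shared vertices from a triangle soup (exact matches).
weld_triangles <- function(tri) {
  if (nrow(tri) %% 3L != 0L) stop("triangle soup length not divisible by 3")
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "_")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  trimesh(tri[uniq, , drop = FALSE], matrix(idx, ncol = 3L, byrow = TRUE))
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len < 1e-30] <- 1
  n / len
}
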