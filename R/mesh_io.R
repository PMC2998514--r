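#' Write a triangle mesh to PLY, OBJ or STL
#'
#' PLY (ascii or binary little-endian) and OBJ preserve vertex coordinates
#' and connectivity on round trip. STL stores per-facet corner coordinates
#' only, so shared-vertex connectivity is lost (reading an STL yields one
#' vertex per facet corner).
#'
#' @param mesh a nonempty [triangle_mesh()].
#' @param path output path.
#' @param format `"ply"`, `"obj"` or `"stl"`; inferred from the extension
#'   when `"auto"`.
#' @param binary for PLY: write binary little-endian (default) or ascii.
#'   STL is always binary; OBJ is always ascii.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, format = c("auto", "ply", "obj", "stl"),
                      binary = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$vertices) == 0 || nrow(mesh$faces) == 0)
    stop("cannot save an empty mesh")
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    if (!ext %in% c("ply", "obj", "stl"))
      stop("unknown mesh format for: ", path)
    format <- ext
  }
  switch(format,
    ply = .write_ply(mesh, path, binary),
    obj = .write_obj(mesh, path),
    stl = .write_stl(mesh, path))
  invisible(path)
}

#' Read a triangle mesh from PLY, OBJ or STL
#'
#' @param path input path.
#' @param format as in [save_mesh()].
#' @return A [triangle_mesh()].
#' @export
load_mesh <- function(path, format = c("auto", "ply", "obj", "stl")) {
  if (!file.exists(path)) stop("cannot read mesh: file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    if (!ext %in% c("ply", "obj", "stl"))
      stop("unknown mesh format for: ", path)
    format <- ext
  }
  switch(format,
    ply = .read_ply(path),
    obj = .read_obj(path),
    stl = .read_stl(path))
}

.write_ply <- function(mesh, path, binary) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  hdr <- c("ply", paste("format", fmt, "1.0"),
           "comment produced by vesselmesh",
           paste("element vertex", nv),
           "property double x", "property double y", "property double z",
           paste("element face", nf),
           "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
    fm <- t(cbind(3L, mesh$faces - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fm[2:4, i]), con, size = 4, endian = "little")
    }
  } else {
    writeLines(apply(mesh$vertices, 1, function(v)
      paste(format(v, digits = 17, trim = TRUE), collapse = " ")), con)
    writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  }
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1, warn = FALSE)
    if (length(ln) == 0) stop("truncated PLY header: ", path)
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  fmt <- sub("^format\\s+(\\S+).*", "\\1", grep("^format", hdr, value = TRUE)[1])
  nv <- as.integer(sub(".*vertex\\s+(\\d+).*", "\\1",
                       grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+(\\d+).*", "\\1",
                       grep("^element face", hdr, value = TRUE)[1]))
  vprops <- grep("^property (double|float)", hdr, value = TRUE)
  vsize <- ifelse(grepl("double", vprops), 8L, 4L)
  if (fmt == "ascii") {
    lines <- readLines(con, warn = FALSE)
    vl <- lines[seq_len(nv)]
    V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[1:3])))
    fl <- lines[nv + seq_len(nf)]
    F <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
      k <- as.integer(x[1])
      if (k != 3) stop("non-triangular PLY face")
      as.integer(x[2:4]) + 1L
    }))
  } else if (fmt == "binary_little_endian") {
    V <- matrix(NA_real_, nv, length(vsize))
    raw_per_v <- sum(vsize)
    buf <- readBin(con, "raw", nv * raw_per_v)
    off <- c(0, cumsum(vsize))
    for (j in seq_along(vsize)) {
      idx <- as.vector(outer(seq_len(vsize[j]) + off[j],
                             (seq_len(nv) - 1) * raw_per_v, "+"))
      V[, j] <- readBin(buf[idx], "numeric", nv, size = vsize[j],
                        endian = "little")
    }
    V <- V[, 1:3, drop = FALSE]
    F <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      k <- as.integer(readBin(con, "raw", 1))
      if (k != 3) stop("non-triangular PLY face")
      F[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  triangle_mesh(V, F)
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(v)
    paste("v", paste(format(v, digits = 17, trim = TRUE), collapse = " "))), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  F <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    ix <- as.integer(sub("/.*", "", x[-1]))
    if (length(ix) != 3) stop("non-triangular OBJ face")
    ix
  }))
  triangle_mesh(V, F)
}

.write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  fn <- .face_normals(mesh$vertices, mesh$faces)
  for (i in seq_len(nf)) {
    writeBin(as.numeric(fn[i, ]), con, size = 4, endian = "little")
    writeBin(as.numeric(t(mesh$vertices[mesh$faces[i, ], ])), con,
             size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

.read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  V <- matrix(NA_real_, nf * 3, 3)
  for (i in seq_len(nf)) {
    readBin(con, "numeric", 3, size = 4, endian = "little")
    V[3 * i - (2:0), ] <- matrix(readBin(con, "numeric", 9, size = 4,
                                         endian = "little"),
                                 3, 3, byrow = TRUE)
    readBin(con, "raw", 2)
  }
  triangle_mesh(V, matrix(seq_len(nf * 3), ncol = 3, byrow = TRUE))
}
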