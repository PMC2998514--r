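#' Binary segmentation volume
#'
#' A `binary_volume` is the pipeline's input container: a 3D occupancy grid
#' (1 = object/vessel, 0 = background) together with per-axis voxel spacing
#' and a world-space origin. The world position of voxel index `(i, j, k)`
#' (0-based) is `origin + c(i, j, k) * spacing`, i.e. voxel centres sit at
#' integer index positions. On construction the grid is binarized (any
#' nonzero value maps to 1) and padded so that at least one full layer of
#' background voxels surrounds the object.
#'
#' @param grid 3D numeric/integer/logical array; nonzero entries become 1.
#' @param spacing length-3 positive numeric, voxel edge lengths per axis.
#' @param origin length-3 numeric, world coordinate of the centre of voxel
#'   `(0, 0, 0)` (before padding; padding shifts the origin accordingly).
#' @return An object of class `binary_volume` with fields `grid`, `spacing`,
#'   `origin`.
#' @export
binary_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L)
    stop("grid must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers")
  g <- array(as.integer(grid != 0), dim = dim(grid))
  if (sum(g) == 0L)
    stop("empty segmentation: volume contains no object voxels")
  v <- structure(list(grid = g, spacing = spacing, origin = origin),
                 class = "binary_volume")
  pad_volume(v)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("binary_volume %d x %d x %d, spacing (%g, %g, %g), %d object voxels\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$grid)))
  invisible(x)
}

#' Ensure a one-voxel background margin
#'
#' Pads the grid with zero layers on any side where an object voxel touches
#' the boundary, shifting the origin so world coordinates are unchanged.
#'
#' @param vol a [binary_volume()].
#' @return The padded `binary_volume`.
#' @export
pad_volume <- function(vol) {
  g <- vol$grid
  d <- dim(g)
  touch_lo <- c(any(g[1, , ] != 0), any(g[, 1, ] != 0), any(g[, , 1] != 0))
  touch_hi <- c(any(g[d[1], , ] != 0), any(g[, d[2], ] != 0), any(g[, , d[3]] != 0))
  if (!any(touch_lo) && !any(touch_hi)) return(vol)
  lo <- as.integer(touch_lo)
  hi <- as.integer(touch_hi)
  nd <- d + lo + hi
  ng <- array(0L, dim = nd)
  ng[(1 + lo[1]):(lo[1] + d[1]),
     (1 + lo[2]):(lo[2] + d[2]),
     (1 + lo[3]):(lo[3] + d[3])] <- g
  vol$grid <- ng
  vol$origin <- vol$origin - lo * vol$spacing
  vol
}

#' World coordinates of voxel centres
#'
#' @param vol a [binary_volume()].
#' @param idx integer matrix (n x 3) of 1-based array indices.
#' @return n x 3 matrix of world coordinates.
#' @export
voxel_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# ---------------------------------------------------------------------------
# Volume file formats: NIfTI (RNifti), MetaImage (.mhd/.mha), raw + JSON.
# ---------------------------------------------------------------------------

#' Load a segmentation volume
#'
#' Reads a 3D scalar volume, binarizes it (nonzero -> 1), reads spacing and
#' origin from the header where the format carries them (defaults 1.0 / 0.0
#' for raw), and guarantees the one-voxel background padding.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format one of `"auto"`, `"nifti"`, `"metaimage"`, `"raw"`. Raw
#'   volumes need a JSON sidecar `<path>.json` with fields `dim` (length 3),
#'   and optionally `spacing`, `origin`, `dtype` (`"uint8"`, `"int16"`,
#'   `"float32"`, `"float64"`).
#' @return A [binary_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "metaimage", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read volume: file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE)) "metaimage"
    else if (grepl("\\.raw$", path, ignore.case = TRUE)) "raw"
    else stop("cannot infer volume format from extension: ", path)
  }
  switch(format,
    nifti = .load_nifti(path),
    metaimage = .load_metaimage(path),
    raw = .load_raw(path))
}

.load_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L) stop("volume is not 3D: ", path)
  sp <- attr(img, "pixdim")[1:3]
  if (is.null(sp) || any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  # world frame: index space scaled by spacing (qform translations ignored;
  # the pipeline's geometry is invariant to a global shift)
  binary_volume(arr, spacing = sp, origin = c(0, 0, 0))
}

.metaimage_dtypes <- c(MET_UCHAR = "uint8", MET_CHAR = "int8",
                       MET_SHORT = "int16", MET_USHORT = "uint16",
                       MET_INT = "int32", MET_UINT = "uint32",
                       MET_FLOAT = "float32", MET_DOUBLE = "float64")

.read_raw_values <- function(con, n, dtype, endian = "little") {
  switch(dtype,
    uint8 = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                               endian = endian)),
    int8 = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE,
                              endian = endian)),
    int16 = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                               endian = endian)),
    uint16 = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                endian = endian)),
    int32 = , uint32 = as.numeric(readBin(con, "integer", n, size = 4,
                                          endian = endian)),
    float32 = readBin(con, "numeric", n, size = 4, endian = endian),
    float64 = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported dtype: ", dtype))
}

.load_metaimage <- function(path) {
  lines <- character()
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  repeat {
    ln <- readLines(con, n = 1, warn = FALSE)
    if (length(ln) == 0) stop("truncated MetaImage header: ", path)
    lines <- c(lines, ln)
    if (grepl("^ElementDataFile", ln)) break
  }
  kv <- strsplit(lines, "\\s*=\\s*")
  hdr <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = " "),
                                character(1)),
                         vapply(kv, `[[`, character(1), 1))
  ndims <- as.integer(hdr[["NDims"]])
  if (!identical(ndims, 3L)) stop("volume is not 3D: ", path)
  dims <- as.integer(strsplit(trimws(hdr[["DimSize"]]), "\\s+")[[1]])
  sp <- if ("ElementSpacing" %in% names(hdr))
    as.numeric(strsplit(trimws(hdr[["ElementSpacing"]]), "\\s+")[[1]]) else c(1, 1, 1)
  org <- if ("Offset" %in% names(hdr))
    as.numeric(strsplit(trimws(hdr[["Offset"]]), "\\s+")[[1]]) else c(0, 0, 0)
  if (isTRUE(toupper(hdr["CompressedData"]) == "TRUE"))
    stop("compressed MetaImage data is not supported")
  dtype <- .metaimage_dtypes[[hdr[["ElementType"]]]]
  if (is.null(dtype)) stop("unsupported MetaImage ElementType")
  endian <- if (isTRUE(toupper(hdr["BinaryDataByteOrderMSB"]) == "TRUE") ||
                isTRUE(toupper(hdr["ElementByteOrderMSB"]) == "TRUE"))
    "big" else "little"
  datafile <- trimws(hdr[["ElementDataFile"]])
  n <- prod(dims)
  if (toupper(datafile) == "LOCAL") {
    vals <- .read_raw_values(con, n, dtype, endian)
  } else {
    dpath <- file.path(dirname(path), datafile)
    dcon <- file(dpath, "rb")
    on.exit(close(dcon), add = TRUE)
    vals <- .read_raw_values(dcon, n, dtype, endian)
  }
  if (length(vals) != n) stop("truncated MetaImage data: ", path)
  binary_volume(array(vals, dim = dims), spacing = sp, origin = org)
}

.load_raw <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    sidecar <- sub("\\.raw$", ".json", path)
  if (!file.exists(sidecar))
    stop("raw volume needs a JSON sidecar: ", path)
  meta <- jsonlite::fromJSON(sidecar)
  dims <- as.integer(meta$dim)
  if (length(dims) != 3L) stop("volume is not 3D: ", path)
  dtype <- if (is.null(meta$dtype)) "uint8" else meta$dtype
  sp <- if (is.null(meta$spacing)) c(1, 1, 1) else as.numeric(meta$spacing)
  org <- if (is.null(meta$origin)) c(0, 0, 0) else as.numeric(meta$origin)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- .read_raw_values(con, prod(dims), dtype)
  if (length(vals) != prod(dims)) stop("truncated raw data: ", path)
  binary_volume(array(vals, dim = dims), spacing = sp, origin = org)
}

#' Save a binary volume
#'
#' Writes NIfTI (via RNifti), uncompressed MetaImage (`.mhd` header +
#' `.raw`, or self-contained `.mha`), or raw bytes with a JSON sidecar.
#'
#' @param vol a [binary_volume()].
#' @param path output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "binary_volume"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(array(as.numeric(vol$grid), dim = dim(vol$grid)))
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE)) {
    local <- grepl("\\.mha$", path, ignore.case = TRUE)
    datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                   ignore.case = TRUE), ".raw")
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False", "CompressedData = False",
             paste("DimSize =", paste(dim(vol$grid), collapse = " ")),
             paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
             paste("Offset =", paste(vol$origin, collapse = " ")),
             "ElementType = MET_UCHAR",
             paste("ElementDataFile =", datafile))
    con <- file(path, "wb")
    writeLines(hdr, con)
    if (local) {
      writeBin(as.raw(vol$grid), con)
      close(con)
    } else {
      close(con)
      dcon <- file(file.path(dirname(path), datafile), "wb")
      writeBin(as.raw(vol$grid), dcon)
      close(dcon)
    }
  } else if (grepl("\\.raw$", path, ignore.case = TRUE)) {
    con <- file(path, "wb")
    writeBin(as.raw(vol$grid), con)
    close(con)
    jsonlite::write_json(
      list(dim = dim(vol$grid), spacing = vol$spacing, origin = vol$origin,
           dtype = "uint8"),
      paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  } else stop("unknown volume format for: ", path)
  invisible(path)
}

#' Euler characteristic of the segmentation's boundary surface
#'
#' Computes the Euler characteristic of the cubical complex spanned by the
#' object voxels (vertices - edges + faces - cubes) and returns twice that
#' value: for a solid body V, the boundary surface satisfies
#' `chi(boundary V) = 2 chi(V)`, i.e. `2 - 2g` per connected component of
#' genus `g`. This is the topology the reconstructed mesh should preserve.
#'
#' @param vol a [binary_volume()].
#' @return integer: the Euler characteristic of the voxel boundary surface.
#' @export
volume_surface_euler <- function(vol) {
  v <- vol$grid != 0L
  d <- dim(v)
  occ <- function(dims, parts) {
    acc <- array(FALSE, dims)
    for (off in parts) {
      sl <- array(FALSE, dims)
      sl[off$di + seq_len(d[1]), off$dj + seq_len(d[2]),
         off$dk + seq_len(d[3])] <- v
      acc <- acc | sl
    }
    sum(acc)
  }
  sh <- function(di, dj, dk) list(di = di, dj = dj, dk = dk)
  N <- sum(v)
  Fx <- occ(d + c(1, 0, 0), list(sh(0, 0, 0), sh(1, 0, 0)))
  Fy <- occ(d + c(0, 1, 0), list(sh(0, 0, 0), sh(0, 1, 0)))
  Fz <- occ(d + c(0, 0, 1), list(sh(0, 0, 0), sh(0, 0, 1)))
  Ex <- occ(d + c(0, 1, 1), list(sh(0, 0, 0), sh(0, 1, 0), sh(0, 0, 1),
                                 sh(0, 1, 1)))
  Ey <- occ(d + c(1, 0, 1), list(sh(0, 0, 0), sh(1, 0, 0), sh(0, 0, 1),
                                 sh(1, 0, 1)))
  Ez <- occ(d + c(1, 1, 0), list(sh(0, 0, 0), sh(1, 0, 0), sh(0, 1, 0),
                                 sh(1, 1, 0)))
  Vc <- occ(d + c(1, 1, 1), list(sh(0, 0, 0), sh(1, 0, 0), sh(0, 1, 0),
                                 sh(0, 0, 1), sh(1, 1, 0), sh(1, 0, 1),
                                 sh(0, 1, 1), sh(1, 1, 1)))
  as.integer(2L * (Vc - (Ex + Ey + Ez) + (Fx + Fy + Fz) - N))
}
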