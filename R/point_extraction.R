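#' Boundary point extraction
#'
#' Converts the object/background interface of a binary volume into a point
#' cloud. One point is generated at the centre of every boundary face (the
#' shared face between an object voxel and a 6-neighbour background voxel).
#' Near thin structures — object voxels erased by a morphological opening
#' with a 3x3x3 box (white top-hat residue) — boundary faces whose outer
#' (background) voxel is 6-adjacent to a thin voxel are refined: the face is
#' split into its four subface quadrants (the interface-facing octant
#' centres), quadrupling the local sampling density.
#'
#' @name point_extraction
NULL

# Shift a 3D array by (di, dj, dk), filling with `fill`.
.shift3 <- function(g, di, dj, dk, fill = 0L) {
  d <- dim(g)
  out <- array(fill, dim = d)
  src_i <- max(1, 1 - di):min(d[1], d[1] - di)
  src_j <- max(1, 1 - dj):min(d[2], d[2] - dj)
  src_k <- max(1, 1 - dk):min(d[3], d[3] - dk)
  out[src_i + di, src_j + dj, src_k + dk] <- g[src_i, src_j, src_k]
  out
}

# 3x3x3 box erosion / dilation on a 0/1 array (index space).
.erode_box3 <- function(g) {
  out <- g
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    out <- pmin(out, .shift3(g, di, dj, dk, fill = 0L))
  }
  out
}

.dilate_box3 <- function(g) {
  out <- g
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    out <- pmax(out, .shift3(g, di, dj, dk, fill = 0L))
  }
  out
}

.dilate_cross6 <- function(g) {
  out <- g
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    out <- pmax(out, .shift3(g, s[1], s[2], s[3], fill = 0L))
  out
}

.face_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))

#' Enumerate boundary faces
#'
#' @param vol a [binary_volume()] (padded on construction).
#' @return data.frame with 1-based object-voxel indices `i, j, k`, the face
#'   `axis` (1..3) and `sign` (+1/-1) pointing from the object voxel to the
#'   background voxel; one row per (object voxel, background 6-neighbour)
#'   pair.
#' @export
find_boundary_faces <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  g <- vol$grid
  out <- vector("list", 6)
  for (f in seq_len(6)) {
    s <- .face_dirs[f, ]
    # voxel is object and neighbour in direction s is background
    nb <- .shift3(g, -s[1], -s[2], -s[3], fill = 0L)  # value of g at x + s
    hit <- which(g == 1L & nb == 0L, arr.ind = TRUE)
    if (nrow(hit) > 0)
      out[[f]] <- data.frame(i = hit[, 1], j = hit[, 2], k = hit[, 3],
                             axis = which(s != 0),
                             sign = s[s != 0])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(i = integer(), j = integer(), k = integer(),
                      axis = integer(), sign = integer())
  rownames(res) <- NULL
  res
}

#' Detect thin-structure voxels (white top-hat)
#'
#' The residue of the volume minus its morphological opening with a 3x3x3
#' box structuring element, applied in index space. Object voxels that the
#' opening cannot reproduce (structures thinner than the element) are
#' flagged.
#'
#' @param vol a [binary_volume()].
#' @return logical 3D array, `TRUE` where the top-hat residue is 1.
#' @export
detect_thin_voxels <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  g <- vol$grid
  opened <- .dilate_box3(.erode_box3(g))
  (g - opened) == 1L
}

#' Extract the boundary point cloud
#'
#' @param vol a [binary_volume()].
#' @return data.frame of boundary samples: world `x, y, z`; the source
#'   object-voxel indices `i, j, k`; `axis`, `sign` of the generating face;
#'   and `is_refined` marking subface samples near thin structures.
#' @export
extract_points <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  faces <- find_boundary_faces(vol)
  thin <- detect_thin_voxels(vol)
  # background voxels 6-adjacent to a thin voxel (centre included; the outer
  # boundary voxel itself is background, never thin)
  thin_adj <- .dilate_cross6(array(as.integer(thin), dim = dim(thin))) == 1L
  d <- dim(vol$grid)
  bg_i <- faces$i + ifelse(faces$axis == 1, faces$sign, 0L)
  bg_j <- faces$j + ifelse(faces$axis == 2, faces$sign, 0L)
  bg_k <- faces$k + ifelse(faces$axis == 3, faces$sign, 0L)
  refined <- thin_adj[cbind(bg_i, bg_j, bg_k)]
  ctr <- voxel_world(vol, cbind(faces$i, faces$j, faces$k))
  off <- matrix(0, nrow(faces), 3)
  off[cbind(seq_len(nrow(faces)), faces$axis)] <-
    0.5 * faces$sign * vol$spacing[faces$axis]
  fc <- ctr + off
  # unrefined faces: one sample at the face centre
  plain <- fc[!refined, , drop = FALSE]
  plain_meta <- faces[!refined, , drop = FALSE]
  # refined faces: four subface-quadrant centres, offset by spacing/4 along
  # the two face-parallel axes
  rf <- which(refined)
  if (length(rf) > 0) {
    ax <- faces$axis[rf]
    other <- matrix(0L, length(rf), 2)
    other[, 1] <- ifelse(ax == 1, 2L, 1L)
    other[, 2] <- ifelse(ax == 3, 2L, 3L)
    quad <- expand.grid(s1 = c(-0.25, 0.25), s2 = c(-0.25, 0.25))
    sub <- vector("list", 4)
    for (q in seq_len(4)) {
      p <- fc[rf, , drop = FALSE]
      p[cbind(seq_along(rf), other[, 1])] <-
        p[cbind(seq_along(rf), other[, 1])] +
        quad$s1[q] * vol$spacing[other[, 1]]
      p[cbind(seq_along(rf), other[, 2])] <-
        p[cbind(seq_along(rf), other[, 2])] +
        quad$s2[q] * vol$spacing[other[, 2]]
      sub[[q]] <- p
    }
    sub_pts <- do.call(rbind, sub)
    sub_meta <- faces[rep(rf, 4), , drop = FALSE]
  } else {
    sub_pts <- matrix(numeric(0), ncol = 3)
    sub_meta <- faces[integer(0), , drop = FALSE]
  }
  out <- data.frame(
    x = c(plain[, 1], sub_pts[, 1]),
    y = c(plain[, 2], sub_pts[, 2]),
    z = c(plain[, 3], sub_pts[, 3]),
    i = c(plain_meta$i, sub_meta$i),
    j = c(plain_meta$j, sub_meta$j),
    k = c(plain_meta$k, sub_meta$k),
    axis = c(plain_meta$axis, sub_meta$axis),
    sign = c(plain_meta$sign, sub_meta$sign),
    is_refined = c(rep(FALSE, nrow(plain)), rep(TRUE, nrow(sub_pts))))
  rownames(out) <- NULL
  out
}
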