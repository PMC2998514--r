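#' Normal estimation by covariance analysis
#'
#' Each boundary sample gets a unit normal from the eigenvector of the
#' 3x3 covariance matrix of its k nearest neighbours (relative to their
#' centroid) that corresponds to the smallest eigenvalue. The sign is then
#' fixed to point *into* the object, toward the sample's source object-voxel
#' centre; ties (normal exactly orthogonal to the inward direction) fall
#' back to the generating face's inward axis.
#'
#' @name normals
NULL

#' k nearest neighbours
#'
#' Euclidean k-NN over a point matrix, excluding each query point itself (by
#' index; coincident duplicates remain eligible). Ties are broken by index
#' order.
#'
#' @param positions n x 3 matrix.
#' @param k neighbour count; `n > k` required.
#' @return n x k integer matrix of 1-based neighbour indices, nearest first.
#' @export
knn <- function(positions, k) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (nrow(positions) <= k)
    stop("point cloud must contain more than k points")
  cpp_knn(positions, as.integer(k))
}

#' Covariance normal of a neighbourhood (unoriented)
#'
#' @param p the sample point (unused by the covariance itself; kept for the
#'   operation's contract).
#' @param neighbors k x 3 matrix of neighbour positions, k >= 3.
#' @return unit vector: the smallest-eigenvalue eigenvector of the neighbour
#'   covariance matrix. Sign is arbitrary at this stage.
#' @export
covariance_normal <- function(p, neighbors) {
  neighbors <- matrix(as.numeric(neighbors), ncol = 3)
  k <- nrow(neighbors)
  if (k < 3) stop("need at least 3 neighbours")
  ctr <- colMeans(neighbors)
  X <- sweep(neighbors, 2, ctr)
  C <- crossprod(X)
  scale <- max(diag(C))
  if (!(scale > 0)) stop("degenerate neighbourhood: all neighbours coincide")
  ev <- eigen(C, symmetric = TRUE)
  # eigenvalues descending; normal = last. Rank < 2 means the neighbourhood
  # is collinear and the normal direction is undefined.
  if (ev$values[2] <= 1e-12 * scale)
    stop("degenerate neighbourhood: neighbours are collinear")
  n <- ev$vectors[, 3]
  n / sqrt(sum(n^2))
}

#' Estimate and orient normals for an extracted point cloud
#'
#' @param samples data.frame from [extract_points()].
#' @param vol the [binary_volume()] the samples came from.
#' @param k neighbour count (default 10).
#' @return An `oriented_point_cloud`: list with `positions` (n x 3),
#'   `normals` (n x 3, unit, inward-facing) and `k`.
#' @export
orient_normals <- function(samples, vol, k = 10) {
  stopifnot(inherits(vol, "binary_volume"))
  P <- cbind(samples$x, samples$y, samples$z)
  nn <- knn(P, k)
  n <- nrow(P)
  N <- matrix(NA_real_, n, 3)
  for (ii in seq_len(n)) {
    N[ii, ] <- covariance_normal(P[ii, ], P[nn[ii, ], , drop = FALSE])
  }
  # inward orientation: toward the source object-voxel centre
  vox <- voxel_world(vol, cbind(samples$i, samples$j, samples$k))
  inward <- vox - P
  dots <- rowSums(N * inward)
  flip <- dots < 0
  N[flip, ] <- -N[flip, ]
  # exact ties: use the face's inward axis (-sign along axis)
  tie <- which(abs(dots) < 1e-12)
  if (length(tie) > 0) {
    face_in <- matrix(0, length(tie), 3)
    face_in[cbind(seq_along(tie), samples$axis[tie])] <- -samples$sign[tie]
    fd <- rowSums(N[tie, , drop = FALSE] * face_in)
    N[tie[fd < 0], ] <- -N[tie[fd < 0], , drop = FALSE]
  }
  structure(list(positions = P, normals = N, k = k,
                 source_voxel = cbind(samples$i, samples$j, samples$k)),
            class = "oriented_point_cloud")
}

#' @export
print.oriented_point_cloud <- function(x, ...) {
  cat(sprintf("oriented_point_cloud: %d points (k = %d)\n",
              nrow(x$positions), x$k))
  invisible(x)
}
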