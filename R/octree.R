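#' Adaptive octree over an oriented point cloud
#'
#' Builds the hierarchical subdivision of the cloud's bounding cube
#' (expanded by `scale`), refined to depth `d` only along cells that contain
#' sample points. The octree provides point location and the depth-d node
#' geometry (centre/width) that carries the indicator-function basis; the
#' Poisson solver itself operates on the complete depth-d node grid (the
#' fully refined level).
#'
#' @param cloud an `oriented_point_cloud` (or any list with `$positions`).
#' @param d maximum depth, between 4 and 10.
#' @param scale bounding-cube expansion factor around the samples.
#' @return An `octree`: list with the cube (`c0` lower corner, `width`),
#'   `depth`, leaf cell size `w`, grid extent `n = 2^d`, and a `nodes`
#'   data.frame (`id`, `depth`, `cx`, `cy`, `cz`, `width`, `parent`,
#'   `is_leaf`) of all adaptively refined nodes.
#' @export
build_octree <- function(cloud, d, scale = 1.25) {
  P <- if (is.matrix(cloud)) cloud else cloud$positions
  if (is.null(P) || nrow(P) == 0) stop("empty point cloud")
  if (d < 4 || d > 10) stop("octree depth must be between 4 and 10")
  lo <- apply(P, 2, min)
  hi <- apply(P, 2, max)
  ctr <- (lo + hi) / 2
  width <- max(hi - lo, 1e-9) * scale
  c0 <- ctr - width / 2
  n <- 2L^d
  w <- width / n
  cell <- function(t) pmin(n - 1L, pmax(0L, as.integer(floor(t))))
  ix <- cell((P[, 1] - c0[1]) / w)
  iy <- cell((P[, 2] - c0[2]) / w)
  iz <- cell((P[, 3] - c0[3]) / w)
  # unique node paths per depth (prefixes of the depth-d cell indices)
  nodes <- vector("list", d + 1)
  nodes[[1]] <- data.frame(depth = 0L, ix = 0L, iy = 0L, iz = 0L)
  for (t in seq_len(d)) {
    sh <- 2L^(d - t)
    u <- unique(data.frame(ix = ix %/% sh, iy = iy %/% sh, iz = iz %/% sh))
    nodes[[t + 1]] <- cbind(depth = t, u)
  }
  tab <- do.call(rbind, nodes)
  tab$width <- width / 2^tab$depth
  tab$cx <- c0[1] + (tab$ix + 0.5) * tab$width
  tab$cy <- c0[2] + (tab$iy + 0.5) * tab$width
  tab$cz <- c0[3] + (tab$iz + 0.5) * tab$width
  tab$id <- seq_len(nrow(tab))
  key <- function(depth, i, j, k) paste(depth, i, j, k)
  idx <- stats::setNames(tab$id, key(tab$depth, tab$ix, tab$iy, tab$iz))
  tab$parent <- ifelse(tab$depth == 0L, NA_integer_,
                       idx[key(tab$depth - 1L, tab$ix %/% 2L,
                               tab$iy %/% 2L, tab$iz %/% 2L)])
  # a node is a leaf iff no node one level deeper has it as parent
  parent_ids <- tab$parent[!is.na(tab$parent)]
  tab$is_leaf <- !(tab$id %in% parent_ids)
  rownames(tab) <- NULL
  structure(list(c0 = c0, width = width, depth = d, w = w, n = n,
                 nodes = tab[, c("id", "depth", "ix", "iy", "iz",
                                 "cx", "cy", "cz", "width", "parent",
                                 "is_leaf")]),
            class = "octree")
}

#' @export
print.octree <- function(x, ...) {
  cat(sprintf("octree: depth %d, %d nodes (%d leaves), cube width %.4g\n",
              x$depth, nrow(x$nodes), sum(x$nodes$is_leaf), x$width))
  invisible(x)
}

#' Locate the depth-d leaf containing each point
#'
#' @param octree an [build_octree()] result.
#' @param pts n x 3 matrix of world points.
#' @return integer vector of node ids (rows of `octree$nodes`), `NA` where
#'   no depth-d leaf of the adaptive tree contains the point.
#' @export
leaf_for_point <- function(octree, pts) {
  pts <- .as_pts(pts)
  t <- sweep(pts, 2, octree$c0) / octree$w
  ci <- floor(t)
  leaves <- octree$nodes[octree$nodes$depth == octree$depth, ]
  key <- paste(leaves$ix, leaves$iy, leaves$iz)
  idx <- stats::setNames(leaves$id, key)
  out <- idx[paste(ci[, 1], ci[, 2], ci[, 3])]
  unname(out)
}
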