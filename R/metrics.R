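#' Mesh quality metrics
#'
#' Evaluation measures for reconstructed surfaces: the edge ratio
#' `tau = |t|_0 / |t|_inf` (minimum over maximum edge length; 1 for
#' equilateral, toward 0 for needles), RMS principal curvature
#' `sqrt((k_max^2 + k_min^2) / 2)` per vertex from a local quadric fit,
#' sampled symmetric surface distances (mean / max / RMS), and topology
#' reports (Euler characteristic, components, boundary edges, manifoldness).
#'
#' @name metrics
NULL

#' Edge ratio of triangles
#'
#' @param vertices n x 3 matrix, or a [triangle_mesh()] (then `faces` is
#'   taken from it).
#' @param faces m x 3 index matrix; when `vertices` is a 3 x 3 matrix of a
#'   single triangle this may be omitted.
#' @return numeric vector of `tau` in (0, 1] per triangle.
#' @export
edge_ratio <- function(vertices, faces = NULL) {
  if (inherits(vertices, "triangle_mesh")) {
    faces <- vertices$faces
    vertices <- vertices$vertices
  }
  if (is.null(faces)) {
    stopifnot(nrow(vertices) == 3)
    faces <- matrix(1:3, 1)
  }
  e1 <- sqrt(rowSums((vertices[faces[, 1], , drop = FALSE] -
                        vertices[faces[, 2], , drop = FALSE])^2))
  e2 <- sqrt(rowSums((vertices[faces[, 2], , drop = FALSE] -
                        vertices[faces[, 3], , drop = FALSE])^2))
  e3 <- sqrt(rowSums((vertices[faces[, 3], , drop = FALSE] -
                        vertices[faces[, 1], , drop = FALSE])^2))
  mx <- pmax(e1, e2, e3)
  if (any(mx == 0)) stop("degenerate triangle with zero-length edge")
  pmin(e1, e2, e3) / mx
}

#' Edge-ratio histogram and tail fractions
#'
#' @param mesh a [triangle_mesh()].
#' @return list with `tau` (per-triangle ratios), `histogram` (counts over
#'   the ten bins `[0, 0.1), ..., [0.9, 1.0]`), and helpers
#'   `fraction_below(tau0)` / `fraction_atleast(tau0)`.
#' @export
edge_ratio_report <- function(mesh) {
  tau <- edge_ratio(mesh)
  breaks <- seq(0, 1, by = 0.1)
  h <- hist(tau, breaks = breaks, plot = FALSE, right = FALSE)
  counts <- h$counts
  counts[10] <- sum(tau >= 0.9)  # last bin [0.9, 1.0] is right-closed
  list(tau = tau,
       histogram = stats::setNames(counts, paste0("[", breaks[-11], ",",
                                                  breaks[-1], ")")),
       fraction_below = function(tau0) mean(tau < tau0),
       fraction_atleast = function(tau0) mean(tau >= tau0))
}

# 1-ring (and optionally 2-ring) neighbour lists from a face matrix.
.vertex_rings <- function(faces, nv) {
  nb <- vector("list", nv)
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  for (r in seq_len(nrow(e))) {
    nb[[e[r, 1]]] <- c(nb[[e[r, 1]]], e[r, 2])
    nb[[e[r, 2]]] <- c(nb[[e[r, 2]]], e[r, 1])
  }
  lapply(nb, unique)
}

#' RMS principal curvature at mesh vertices
#'
#' Fits a quadric height function over the vertex's neighbourhood (1-ring,
#' extended to the 2-ring when under-determined) in the local normal frame,
#' derives the principal curvatures from the Weingarten map, and returns
#' `sqrt((k_max^2 + k_min^2)/2)` per vertex. Rank-deficient fits yield 0
#' with an NA-flag attribute.
#'
#' @param mesh a [triangle_mesh()].
#' @param vertices which vertices to evaluate (default all).
#' @return numeric vector of RMS curvature values; attribute `flat_flag`
#'   marks vertices where the fit was degenerate.
#' @export
rms_curvature <- function(mesh, vertices = NULL) {
  V <- mesh$vertices
  F <- mesh$faces
  nv <- nrow(V)
  if (is.null(vertices)) vertices <- seq_len(nv)
  rings <- .vertex_rings(F, nv)
  # area-weighted vertex normals from face normals
  fn <- .face_normals(V, F)
  ar <- .tri_area(V, F)
  VN <- matrix(0, nv, 3)
  for (c in 1:3) {
    for (ax in 1:3) {
      s <- rowsum(fn[, ax] * ar, F[, c])
      ii <- as.integer(rownames(s))
      VN[ii, ax] <- VN[ii, ax] + s[, 1]
    }
  }
  VN <- VN / pmax(sqrt(rowSums(VN^2)), 1e-300)
  out <- numeric(length(vertices))
  flat <- logical(length(vertices))
  for (vi in seq_along(vertices)) {
    v <- vertices[vi]
    nb <- rings[[v]]
    if (length(nb) < 5) {
      nb <- unique(c(nb, unlist(rings[nb])))
      nb <- setdiff(nb, v)
    }
    if (length(nb) < 5) { out[vi] <- 0; flat[vi] <- TRUE; next }
    n <- VN[v, ]
    e1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * n) * n; e1 <- e1 / .vnorm(e1)
    e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    Q <- sweep(V[nb, , drop = FALSE], 2, V[v, ])
    x <- Q %*% e1; y <- Q %*% e2; h <- Q %*% n
    X <- cbind(x, y, x^2, x * y, y^2)
    fit <- tryCatch(qr.coef(qr(X), h), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit))) { out[vi] <- 0; flat[vi] <- TRUE; next }
    hx <- fit[1]; hy <- fit[2]
    hxx <- 2 * fit[3]; hxy <- fit[4]; hyy <- 2 * fit[5]
    W <- sqrt(1 + hx^2 + hy^2)
    I1 <- matrix(c(1 + hx^2, hx * hy, hx * hy, 1 + hy^2), 2)
    I2 <- matrix(c(hxx, hxy, hxy, hyy), 2) / W
    S <- solve(I1, I2)
    k <- Re(eigen(S, only.values = TRUE)$values)
    out[vi] <- sqrt(sum(k^2) / 2)
  }
  attr(out, "flat_flag") <- flat
  out
}

.sample_on_mesh <- function(mesh, samples_per_triangle) {
  V <- mesh$vertices
  F <- mesh$faces
  pts <- V
  if (samples_per_triangle > 0 && nrow(F) > 0) {
    m <- nrow(F) * samples_per_triangle
    fidx <- rep(seq_len(nrow(F)), each = samples_per_triangle)
    r1 <- sqrt(stats::runif(m))
    r2 <- stats::runif(m)
    w1 <- 1 - r1
    w2 <- r1 * (1 - r2)
    w3 <- r1 * r2
    pts <- rbind(pts,
                 w1 * V[F[fidx, 1], , drop = FALSE] +
                   w2 * V[F[fidx, 2], , drop = FALSE] +
                   w3 * V[F[fidx, 3], , drop = FALSE])
  }
  pts
}

#' Sampled symmetric surface distance
#'
#' Samples points on mesh A (all vertices plus uniform interior samples)
#' and measures each to the reference (exact point-to-triangle distance for
#' a mesh reference, |signed distance| for an analytic reference), and vice
#' versa; mean, max and RMS are taken over the pooled directed distances.
#'
#' @param mesh a [triangle_mesh()].
#' @param reference a [triangle_mesh()] or an `analytic_shape`.
#' @param samples_per_triangle interior sample density (plus all vertices).
#' @param n_reference_samples for an analytic reference: number of surface
#'   points drawn for the reverse direction.
#' @return list with `mean`, `max`, `rms` and the pooled sample count `n`.
#' @export
surface_distance <- function(mesh, reference, samples_per_triangle = 10,
                             n_reference_samples = 20000) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0) stop("empty mesh")
  ptsA <- .sample_on_mesh(mesh, samples_per_triangle)
  if (inherits(reference, "triangle_mesh")) {
    dA <- cpp_point_mesh_dist(ptsA, reference$vertices, reference$faces)
    ptsB <- .sample_on_mesh(reference, samples_per_triangle)
    dB <- cpp_point_mesh_dist(ptsB, mesh$vertices, mesh$faces)
  } else if (inherits(reference, "analytic_shape")) {
    dA <- abs(signed_distance(reference, ptsA))
    ptsB <- sample_surface(reference, n_reference_samples)
    dB <- cpp_point_mesh_dist(ptsB, mesh$vertices, mesh$faces)
  } else stop("reference must be a triangle_mesh or an analytic_shape")
  d <- c(dA, dB)
  if (length(d) == 0) stop("empty sample set")
  list(mean = mean(d), max = max(d), rms = sqrt(mean(d^2)), n = length(d))
}

#' Topology and manifoldness report
#'
#' @param mesh a [triangle_mesh()].
#' @return list: `euler` (V - E + F), `components` (of the face graph),
#'   `boundary_edges` (edges with exactly one incident face), `manifold`
#'   (every edge has at most two incident faces and every vertex star is a
#'   single fan), `oriented` (no directed edge repeats and every interior
#'   edge is traversed in opposite directions).
#' @export
topology_report <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  nf <- nrow(F)
  if (nf == 0)
    return(list(euler = nrow(V), components = 0L, boundary_edges = 0L,
                manifold = TRUE, oriented = TRUE))
  ed <- .mesh_edges(F)
  key <- paste0(ed$a, ",", ed$b)
  cnt <- table(key)
  n_edges <- length(cnt)
  used_v <- length(unique(as.vector(F)))
  euler <- used_v - n_edges + nf
  boundary_edges <- sum(cnt == 1)
  edge_manifold <- all(cnt <= 2)
  # orientation: each directed edge at most once
  tails <- c(F[, 1], F[, 2], F[, 3])
  heads <- c(F[, 2], F[, 3], F[, 1])
  oriented <- !anyDuplicated(paste0(tails, ",", heads))
  # components of the face graph (union-find over faces sharing an edge)
  parent <- seq_len(nf)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sp <- split(ed$face, key)
  for (fs in sp) {
    if (length(fs) > 1)
      for (i in 2:length(fs)) {
        a <- find(fs[1]); b <- find(fs[i])
        if (a != b) parent[b] <- a
      }
  }
  components <- length(unique(vapply(seq_len(nf), find, integer(1))))
  # vertex stars: single fan <=> the faces incident to each vertex form one
  # connected component under "shares an edge at that vertex" (detects
  # bowtie vertices that pure edge/face counting misses)
  vertex_manifold <- edge_manifold
  if (edge_manifold) {
    corner_v <- as.vector(F)
    corner_f <- rep(seq_len(nf), 3)
    by_v <- split(corner_f, corner_v)
    for (v in names(by_v)) {
      fs <- by_v[[v]]
      if (length(fs) <= 1) next
      vv <- as.integer(v)
      lp <- stats::setNames(seq_along(fs), fs)
      lfind <- function(i) {
        while (lp[i] != i) { lp[i] <<- lp[lp[i]]; i <- lp[i] }
        i
      }
      emap <- list()
      for (fi in seq_along(fs)) {
        others <- setdiff(F[fs[fi], ], vv)
        for (u in others) {
          ku <- as.character(u)
          prev <- emap[[ku]]
          if (is.null(prev)) emap[[ku]] <- fi
          else {
            a <- lfind(prev); b <- lfind(fi)
            if (a != b) lp[b] <- a
          }
        }
      }
      roots <- unique(vapply(seq_along(fs), lfind, integer(1)))
      if (length(roots) > 1) { vertex_manifold <- FALSE; break }
    }
  }
  list(euler = euler, components = components,
       boundary_edges = as.integer(boundary_edges),
       manifold = edge_manifold && vertex_manifold,
       oriented = oriented)
}
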