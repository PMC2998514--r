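# Analytic test meshes built in code: icosphere, planar grid, cylinder and
# torus grids. Used as references for curvature, distance and topology
# checks.

make_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  triangle_mesh(V, F)
}

make_icosphere <- function(subdiv = 2, radius = 1, center = c(0, 0, 0)) {
  mesh <- make_icosahedron()
  V <- mesh$vertices
  F <- mesh$faces
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      m <- (V[a, ] + V[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      V <<- rbind(V, m)
      mid_cache[[key]] <- nrow(V)
      nrow(V)
    }
    newF <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                    c(ab, bc, ca))
    }
    F <- newF
  }
  triangle_mesh(sweep(V * radius, 2, center, "+"), F)
}

make_plane_grid <- function(n = 10, spacing = 1) {
  xs <- (0:n) * spacing
  V <- as.matrix(expand.grid(x = xs, y = xs))
  V <- cbind(V, 0)
  idx <- function(i, j) i + (n + 1) * (j - 1)
  F <- matrix(0L, 0, 3)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    F <- rbind(F, c(a, b, c), c(a, c, d))
  }
  triangle_mesh(V, F)
}

make_cylinder_grid <- function(radius = 5, height = 20, n_theta = 40,
                               n_z = 20) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(0, height, length.out = n_z + 1)
  V <- matrix(0, 0, 3)
  for (z in zs)
    V <- rbind(V, cbind(radius * cos(th), radius * sin(th), z))
  idx <- function(i, j) ((j - 1) * n_theta) + ((i - 1) %% n_theta) + 1
  F <- matrix(0L, 0, 3)
  for (j in seq_len(n_z)) for (i in seq_len(n_theta)) {
    a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    F <- rbind(F, c(a, b, c), c(a, c, d))
  }
  triangle_mesh(V, F)
}

make_torus_grid <- function(R_major = 10, r_minor = 3, n_u = 36, n_v = 18) {
  us <- seq(0, 2 * pi, length.out = n_u + 1)[-(n_u + 1)]
  vs <- seq(0, 2 * pi, length.out = n_v + 1)[-(n_v + 1)]
  V <- matrix(0, 0, 3)
  for (v in vs)
    V <- rbind(V, cbind((R_major + r_minor * cos(v)) * cos(us),
                        (R_major + r_minor * cos(v)) * sin(us),
                        r_minor * sin(v)))
  idx <- function(i, j) (((j - 1) %% n_v) * n_u) + ((i - 1) %% n_u) + 1
  F <- matrix(0L, 0, 3)
  for (j in seq_len(n_v)) for (i in seq_len(n_u)) {
    a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    F <- rbind(F, c(a, b, c), c(a, c, d))
  }
  triangle_mesh(V, F)
}

# A small binary volume with a single object voxel in the middle.
single_voxel_volume <- function() {
  g <- array(0L, dim = c(5, 5, 5))
  g[3, 3, 3] <- 1L
  binary_volume(g)
}
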