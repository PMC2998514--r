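#' Triangle mesh container
#'
#' A `triangle_mesh` holds world-space vertices (`n x 3` numeric matrix) and
#' faces (`m x 3` integer matrix of 1-based vertex indices with consistent
#' winding). Optionally carries per-vertex `normals`.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix, 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit vertex normals.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Undirected edge table: one row per face edge, with a canonical key.
.mesh_edges <- function(faces) {
  if (nrow(faces) == 0)
    return(data.frame(a = integer(), b = integer(), face = integer()))
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  data.frame(a = pmin(e[, 1], e[, 2]), b = pmax(e[, 1], e[, 2]),
             face = rep(seq_len(nrow(faces)), 3))
}

.face_normals <- function(V, F) {
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  v <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

.tri_area <- function(V, F) {
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  v <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(n^2))
}
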