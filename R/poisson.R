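#' Poisson indicator function
#'
#' The indicator function psi (roughly 1 inside the object, 0 outside) is
#' recovered from the oriented point cloud by solving the Poisson problem
#' `Laplacian psi = div V`, where the vector field V is the inward normal
#' field splatted onto the depth-d node grid with trilinear weights. Each
#' node carries a unit-integral basis function: the tensor-product quadratic
#' B-spline centred at the node and scaled by its width — the standard
#' compactly supported approximation of the unit-variance Gaussian used in
#' Poisson surface reconstruction. The Galerkin normal equations
#' `sum_o c_o <grad F_i, grad F_o> = <grad F_i, V>` are solved matrix-free
#' by conjugate gradients: on the regular node grid the stiffness operator
#' is a separable 5-point stencil per axis.
#'
#' @name poisson_field
NULL

# Exact 1D overlap integrals of the quadratic B-spline on the unit grid,
# offsets m = -2..2:
#   .BM = int b(t) b(t-m) dt, .BG = int b'(t) b'(t-m) dt,
#   .BD = int b(t-m) b'(t) dt (antisymmetric).
.BM <- c(1 / 120, 13 / 60, 11 / 20, 13 / 60, 1 / 120)
.BG <- c(-1 / 6, -1 / 3, 1, -1 / 3, -1 / 6)
.BD <- c(1 / 24, 5 / 12, 0, -5 / 12, -1 / 24)

#' Basis function of an octree node
#'
#' `F_o(q) = F((q - c)/w) / w^3` with `F` the tensor-product quadratic
#' B-spline; unit integral over its support (the `3w`-wide box around `c`),
#' zero outside.
#'
#' @param node list (or one-row data.frame) with `center` (or `cx, cy, cz`)
#'   and `width`.
#' @param q n x 3 matrix (or length-3 vector) of world points.
#' @return numeric vector of basis values.
#' @export
basis_value <- function(node, q) {
  ctr <- if (!is.null(node$center)) as.numeric(node$center)
         else c(node$cx, node$cy, node$cz)
  w <- as.numeric(node$width)
  q <- .as_pts(q)
  t <- sweep(q, 2, ctr) / w
  .bsp2(t[, 1]) * .bsp2(t[, 2]) * .bsp2(t[, 3]) / w^3
}

.bsp2 <- function(t) {
  a <- abs(t)
  ifelse(a >= 1.5, 0, ifelse(a <= 0.5, 0.75 - t^2, 0.5 * (1.5 - a)^2))
}

#' Splat the inward normal field onto the depth-d node grid
#'
#' Each sample distributes its inward unit normal over the 8 nearest depth-d
#' nodes with trilinear weights (summing to 1).
#'
#' @param cloud an `oriented_point_cloud`.
#' @param octree an [build_octree()] result.
#' @return list of three `n^3` arrays `Vx, Vy, Vz` of node vector
#'   coefficients.
#' @export
splat_vector_field <- function(cloud, octree) {
  P <- cloud$positions
  N <- cloud$normals
  n <- octree$n
  w <- octree$w
  # node-centre coordinates: node i centred at c0 + (i + 0.5) w
  t <- sweep(P, 2, octree$c0) / w - 0.5
  if (any(t < -0.5 - 1e-9) || any(t > n - 0.5 + 1e-9))
    stop("sample outside octree bounds")
  base <- pmin(pmax(floor(t), 0L), n - 2L)  # argument order keeps dim()
  fr <- t - base
  dims <- c(n, n, n)
  acc <- function(arr, idx, val) {
    s <- rowsum(val, idx)
    ii <- as.integer(rownames(s))
    arr[ii] <- arr[ii] + s[, 1]
    arr
  }
  Vx <- array(0, dims); Vy <- array(0, dims); Vz <- array(0, dims)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wgt <- (if (cx == 1) fr[, 1] else 1 - fr[, 1]) *
           (if (cy == 1) fr[, 2] else 1 - fr[, 2]) *
           (if (cz == 1) fr[, 3] else 1 - fr[, 3])
    idx <- (base[, 1] + cx) + n * (base[, 2] + cy) +
      n * n * (base[, 3] + cz) + 1
    Vx <- acc(Vx, idx, wgt * N[, 1])
    Vy <- acc(Vy, idx, wgt * N[, 2])
    Vz <- acc(Vz, idx, wgt * N[, 3])
  }
  list(Vx = Vx, Vy = Vy, Vz = Vz)
}

# Stiffness operator (1/w^5 scale omitted; folded into the solve, where the
# right-hand side carries the matching 1/w^4 — only the ratio matters for
# the linear system, and both sides are scaled consistently below).
.stiffness_apply <- function(x, dims) {
  cpp_conv3_sep(x, dims, .BG, .BM, .BM) +
    cpp_conv3_sep(x, dims, .BM, .BG, .BM) +
    cpp_conv3_sep(x, dims, .BM, .BM, .BG)
}

#' Solve the Poisson system for the basis coefficients
#'
#' Conjugate gradients on the Galerkin normal equations, matrix-free.
#'
#' @param octree an [build_octree()] result.
#' @param vfield output of [splat_vector_field()].
#' @param tol relative residual tolerance.
#' @param maxit iteration cap; default `10 * sqrt(#unknowns) + 1000`.
#' @return `n^3` array of basis coefficients.
#' @export
solve_poisson <- function(octree, vfield, tol = 1e-8, maxit = NULL) {
  n <- octree$n
  dims <- c(n, n, n)
  w <- octree$w
  # rhs_i = <grad F_i, V> = (1/w^4) sum_axis conv(V_axis; -D on axis, M others)
  b <- -(cpp_conv3_sep(vfield$Vx, dims, .BD, .BM, .BM) +
           cpp_conv3_sep(vfield$Vy, dims, .BM, .BD, .BM) +
           cpp_conv3_sep(vfield$Vz, dims, .BM, .BM, .BD))
  # stiffness carries 1/w^5, rhs 1/w^4: scale rhs by w so that the solved
  # coefficients correspond to the physical system
  b <- b * w
  nb <- sqrt(sum(b^2))
  x <- array(0, dims)
  if (nb == 0) return(x)
  if (is.null(maxit)) maxit <- ceiling(10 * sqrt(length(x)) + 1000)
  r <- b
  p <- r
  rs <- sum(r^2)
  for (it in seq_len(maxit)) {
    Ap <- .stiffness_apply(p, dims)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0) stop("Poisson solver diverged")
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (!is.finite(rs_new)) stop("Poisson solver diverged")
    if (sqrt(rs_new) <= tol * nb) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (sqrt(rs_new <- sum(r^2)) > tol * nb)
    warning(sprintf("conjugate gradients hit the iteration cap (%d); relative residual %.3g",
                    maxit, sqrt(rs_new) / nb))
  x
}

#' Compute the full implicit field from an oriented point cloud
#'
#' Builds the octree, splats the normal field, solves the Poisson system and
#' selects the isovalue as the mean of psi over the sample positions.
#'
#' @param cloud an `oriented_point_cloud`.
#' @param depth octree depth d (4..10; memory grows as `8^d`).
#' @param scale bounding-cube expansion factor.
#' @param tol,maxit conjugate-gradient controls, see [solve_poisson()].
#' @return An `implicit_field`: coefficients, grid geometry, `isovalue`,
#'   `psi_scale` (span of psi used for projection tolerances) and the
#'   `octree`.
#' @export
poisson_field <- function(cloud, depth = 7, scale = 1.25, tol = 1e-8,
                          maxit = NULL) {
  octree <- build_octree(cloud, depth, scale)
  vf <- splat_vector_field(cloud, octree)
  coef <- solve_poisson(octree, vf, tol = tol, maxit = maxit)
  fld <- structure(list(coef = coef, n = octree$n, c0 = octree$c0,
                        w = octree$w, width = octree$width, depth = depth,
                        octree = octree, isovalue = 0, psi_scale = 1),
                   class = "implicit_field")
  psi_s <- evaluate_field(fld, cloud$positions)$psi
  fld$isovalue <- mean(psi_s)
  ctr <- matrix(octree$c0 + octree$width / 2, 1, 3)
  probe <- rbind(ctr, cloud$positions[seq(1, nrow(cloud$positions),
                                          length.out = min(64, nrow(cloud$positions))), ])
  span <- diff(range(c(psi_s, evaluate_field(fld, probe)$psi)))
  fld$psi_scale <- max(span, .Machine$double.eps)
  fld
}

#' @export
print.implicit_field <- function(x, ...) {
  cat(sprintf("implicit_field: depth %d (%d^3 nodes), isovalue %.4g\n",
              x$depth, x$n, x$isovalue))
  invisible(x)
}

#' Evaluate psi and its gradient
#'
#' @param field an `implicit_field`.
#' @param x n x 3 matrix (or length-3 vector) of world points inside the
#'   octree bounds.
#' @return list with `psi` (numeric vector) and `grad` (n x 3 matrix).
#' @export
evaluate_field <- function(field, x) {
  x <- .as_pts(x)
  lo <- field$c0
  hi <- field$c0 + field$width
  if (any(sweep(x, 2, lo) < -1e-9) || any(sweep(x, 2, hi) > 1e-9))
    stop("point outside octree bounds")
  out <- cpp_field_eval(field$coef, rep(field$n, 3), field$c0, field$w, x)
  list(psi = out[, 1], grad = out[, 2:4, drop = FALSE])
}

#' Isovalue selection: mean psi over the sample positions
#'
#' @param field an `implicit_field`.
#' @param cloud the `oriented_point_cloud` the field was solved from.
#' @return scalar isovalue.
#' @export
select_isovalue <- function(field, cloud) {
  mean(evaluate_field(field, cloud$positions)$psi)
}
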