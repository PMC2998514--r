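#' Analytic phantom shapes
#'
#' Phantoms are analytic solids with exact signed-distance functions
#' (negative inside), used to rasterize test volumes with known ground-truth
#' surfaces. Supported kinds: sphere, tube (capsule: a cylinder with
#' hemispherical caps), torus (axis z), Y-bifurcation (union of two tubes
#' sharing a junction point), dumbbell (two spheres joined by a tube), and an
#' axis-aligned box.
#'
#' `signed_distance()` is exact for each primitive; compound shapes take the
#' pointwise minimum over their parts, which is the exact signed distance
#' everywhere except inside overlap regions (where it remains a valid
#' inside-indicator and a lower bound on the distance to the union surface).
#'
#' @name phantoms
NULL

.shape <- function(kind, params, sdf, bounds) {
  structure(list(kind = kind, params = params, sdf = sdf, bounds = bounds),
            class = "analytic_shape")
}

#' @export
print.analytic_shape <- function(x, ...) {
  cat(sprintf("analytic_shape: %s\n", x$kind))
  invisible(x)
}

.as_pts <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  p
}

#' Signed distance from world points to a shape
#'
#' @param shape an `analytic_shape`.
#' @param pts n x 3 matrix (or length-3 vector) of world points.
#' @return numeric vector of signed distances, negative inside.
#' @export
signed_distance <- function(shape, pts) {
  stopifnot(inherits(shape, "analytic_shape"))
  shape$sdf(.as_pts(pts))
}

#' @rdname phantoms
#' @param center,radius sphere centre and radius.
#' @export
shape_sphere <- function(center = c(0, 0, 0), radius) {
  stopifnot(radius > 0)
  center <- as.numeric(center)
  .shape("sphere", list(center = center, radius = radius),
         function(p) sqrt(rowSums(sweep(p, 2, center)^2)) - radius,
         rbind(center - radius, center + radius))
}

.seg_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  ap <- sweep(p, 2, a)
  t <- pmin(1, pmax(0, (ap %*% ab) / max(len2, 1e-300)))
  q <- ap - outer(as.numeric(t), ab)
  sqrt(rowSums(q^2))
}

#' @rdname phantoms
#' @param a,b tube axis endpoints (capsule cap centres).
#' @param r tube radius.
#' @export
shape_tube <- function(a, b, r) {
  stopifnot(r > 0)
  a <- as.numeric(a); b <- as.numeric(b)
  .shape("tube", list(a = a, b = b, r = r),
         function(p) .seg_dist(p, a, b) - r,
         rbind(pmin(a, b) - r, pmax(a, b) + r))
}

#' @rdname phantoms
#' @param R_major distance from torus centre to the tube centreline.
#' @param r_minor tube radius of the torus.
#' @export
shape_torus <- function(center = c(0, 0, 0), R_major, r_minor) {
  stopifnot(R_major > r_minor, r_minor > 0)
  center <- as.numeric(center)
  .shape("torus", list(center = center, R_major = R_major, r_minor = r_minor),
         function(p) {
           q <- sweep(p, 2, center)
           rho <- sqrt(q[, 1]^2 + q[, 2]^2)
           sqrt((rho - R_major)^2 + q[, 3]^2) - r_minor
         },
         rbind(center - c(R_major + r_minor, R_major + r_minor, r_minor),
               center + c(R_major + r_minor, R_major + r_minor, r_minor)))
}

#' Union of shapes (pointwise minimum of signed distances)
#'
#' @param ... `analytic_shape` objects.
#' @export
shape_union <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, logical(1), "analytic_shape")))
  bl <- do.call(rbind, lapply(parts, function(s) s$bounds[1, ]))
  bh <- do.call(rbind, lapply(parts, function(s) s$bounds[2, ]))
  sh <- .shape("union", list(parts = parts),
               function(p) {
                 d <- do.call(cbind, lapply(parts, function(s) s$sdf(p)))
                 do.call(pmin, as.data.frame(d))
               },
               rbind(apply(bl, 2, min), apply(bh, 2, max)))
  sh
}

#' @rdname phantoms
#' @param junction world point where the two tube axes meet.
#' @param angle_deg full angle between the two tube axes, in degrees.
#' @param length length of each tube segment from the junction.
#' @export
shape_bifurcation <- function(junction = c(0, 0, 0), r = 6, angle_deg = 60,
                              length = 25) {
  half <- angle_deg / 2 * pi / 180
  d1 <- c(sin(half), 0, cos(half))
  d2 <- c(-sin(half), 0, cos(half))
  junction <- as.numeric(junction)
  sh <- shape_union(shape_tube(junction, junction + length * d1, r),
                    shape_tube(junction, junction + length * d2, r))
  sh$kind <- "bifurcation"
  sh$params <- c(sh$params, list(junction = junction, r = r,
                                 angle_deg = angle_deg, length = length))
  sh
}

#' @rdname phantoms
#' @param c1,c2 sphere centres of the dumbbell.
#' @param R1,R2 sphere radii of the dumbbell.
#' @param neck_r radius of the connecting tube.
#' @export
shape_dumbbell <- function(c1 = c(0, 0, 0), c2 = c(28, 0, 0), R1 = 15, R2 = 5,
                           neck_r = 3) {
  sh <- shape_union(shape_sphere(c1, R1), shape_sphere(c2, R2),
                    shape_tube(c1, c2, neck_r))
  sh$kind <- "dumbbell"
  sh$params <- c(sh$params, list(c1 = c1, c2 = c2, R1 = R1, R2 = R2,
                                 neck_r = neck_r))
  sh
}

#' @rdname phantoms
#' @param lo,hi opposite corners of an axis-aligned box.
#' @export
shape_box <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(all(hi > lo))
  ctr <- (lo + hi) / 2
  half <- (hi - lo) / 2
  .shape("box", list(lo = lo, hi = hi),
         function(p) {
           q <- abs(sweep(p, 2, ctr)) - matrix(half, nrow(p), 3, byrow = TRUE)
           outside <- sqrt(rowSums(pmax(q, 0)^2))
           inside <- pmin(apply(q, 1, max), 0)
           outside + inside
         },
         rbind(lo, hi))
}

#' Rasterize an analytic shape into a binary volume
#'
#' A voxel is set to 1 exactly when its centre lies strictly inside the shape
#' (signed distance < 0). The grid covers the shape's bounding box plus a
#' background margin; construction then guarantees the one-voxel zero
#' padding.
#'
#' @param shape an `analytic_shape`.
#' @param spacing per-axis voxel edge lengths.
#' @param margin number of background voxels around the bounding box
#'   (must be >= 1).
#' @return A [binary_volume()].
#' @export
rasterize <- function(shape, spacing = c(1, 1, 1), margin = 2) {
  stopifnot(inherits(shape, "analytic_shape"), margin >= 1)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(!is.finite(shape$bounds)))
    stop("cannot rasterize an unbounded shape")
  # align voxel centres to the spacing lattice, so the same shape always
  # rasterizes onto the same grid positions regardless of its bounds
  lo <- spacing * floor((shape$bounds[1, ] - margin * spacing) / spacing)
  hi <- shape$bounds[2, ] + margin * spacing
  dims <- pmax(3L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  xs <- lo[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- lo[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- lo[3] + (seq_len(dims[3]) - 1) * spacing[3]
  pts <- cbind(rep(xs, times = dims[2] * dims[3]),
               rep(rep(ys, each = dims[1]), times = dims[3]),
               rep(zs, each = dims[1] * dims[2]))
  inside <- signed_distance(shape, pts) < 0
  if (!any(inside)) stop("shape rasterized to an empty volume")
  binary_volume(array(as.integer(inside), dim = dims),
                spacing = spacing, origin = lo)
}

#' Sample points uniformly on a shape's surface
#'
#' Used by the surface-distance metric when the reference is analytic. For
#' compound shapes, points are drawn on each part (area-weighted) and
#' rejected when they fall strictly inside the union.
#'
#' @param shape an `analytic_shape`.
#' @param n number of points requested (the result may be slightly smaller
#'   for unions after rejection).
#' @return m x 3 matrix of surface points.
#' @export
sample_surface <- function(shape, n) {
  stopifnot(inherits(shape, "analytic_shape"), n >= 1)
  kind <- shape$kind
  if (kind == "sphere") {
    ctr <- shape$params$center; R <- shape$params$radius
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    return(sweep(R * v, 2, ctr, "+"))
  }
  if (kind == "tube") {
    a <- shape$params$a; b <- shape$params$b; r <- shape$params$r
    L <- sqrt(sum((b - a)^2))
    area_cyl <- 2 * pi * r * L
    area_caps <- 4 * pi * r^2
    n_cyl <- stats::rbinom(1, n, area_cyl / (area_cyl + area_caps))
    ax <- (b - a) / L
    e1 <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ax[2] * e1[3] - ax[3] * e1[2], ax[3] * e1[1] - ax[1] * e1[3],
            ax[1] * e1[2] - ax[2] * e1[1])
    pts <- NULL
    if (n_cyl > 0) {
      t <- stats::runif(n_cyl); th <- stats::runif(n_cyl, 0, 2 * pi)
      pts <- sweep(outer(t * L, ax) + r * (outer(cos(th), e1) + outer(sin(th), e2)),
                   2, a, "+")
    }
    n_cap <- n - n_cyl
    if (n_cap > 0) {
      v <- matrix(stats::rnorm(3 * n_cap), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      along <- as.numeric(v %*% ax)
      ctrs <- t(vapply(along, function(s) if (s >= 0) b else a, numeric(3)))
      pts <- rbind(pts, ctrs + r * v)
    }
    return(pts)
  }
  if (kind == "torus") {
    ctr <- shape$params$center; R <- shape$params$R_major; r <- shape$params$r_minor
    # area element prop. to (R + r cos v): rejection on v
    out <- matrix(numeric(0), ncol = 3)
    while (nrow(out) < n) {
      m <- 2 * (n - nrow(out)) + 16
      u <- stats::runif(m, 0, 2 * pi)
      v <- stats::runif(m, 0, 2 * pi)
      keep <- stats::runif(m) < (R + r * cos(v)) / (R + r)
      u <- u[keep]; v <- v[keep]
      p <- cbind((R + r * cos(v)) * cos(u), (R + r * cos(v)) * sin(u),
                 r * sin(v))
      out <- rbind(out, sweep(p, 2, ctr, "+"))
    }
    return(out[seq_len(n), , drop = FALSE])
  }
  # compound: area-weighted over parts with rejection inside the union
  parts <- shape$params$parts
  if (is.null(parts)) stop("no surface sampler for shape kind: ", kind)
  areas <- vapply(parts, .shape_area, numeric(1))
  out <- matrix(numeric(0), ncol = 3)
  guard <- 0
  while (nrow(out) < n && guard < 50) {
    m <- n - nrow(out)
    counts <- stats::rmultinom(1, m + 16, areas / sum(areas))[, 1]
    for (i in seq_along(parts)) {
      if (counts[i] == 0) next
      p <- sample_surface(parts[[i]], counts[i])
      keep <- signed_distance(shape, p) > -1e-9
      out <- rbind(out, p[keep, , drop = FALSE])
    }
    guard <- guard + 1
  }
  out[seq_len(min(n, nrow(out))), , drop = FALSE]
}

.shape_area <- function(shape) {
  switch(shape$kind,
    sphere = 4 * pi * shape$params$radius^2,
    tube = {
      L <- sqrt(sum((shape$params$b - shape$params$a)^2))
      2 * pi * shape$params$r * L + 4 * pi * shape$params$r^2
    },
    torus = 4 * pi^2 * shape$params$R_major * shape$params$r_minor,
    stop("no area for shape kind: ", shape$kind))
}
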