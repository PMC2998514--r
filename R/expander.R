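#' Curvature-adaptive mesh expansion
#'
#' Polygonizes the implicit isosurface by growing triangles from boundary
#' edges. A seed hexagon is built in the tangent plane of a projected start
#' point, sized to `rho * r` where `r` is the local radius of curvature
#' (estimated from chord lengths and normal deviations). Expansion pops
#' boundary edges from a FIFO queue: adjacent boundary edges meeting at less
#' than 70 degrees are closed with an "ear" triangle from existing vertices;
#' otherwise a candidate vertex is placed opposite the owning triangle,
#' sized to `rho * r`, projected to the surface, and accepted when both base
#' angles lie in [50, 70] degrees and the new triangle does not approach any
#' boundary triangle closer than one third of the longest edge involved.
#' Edges whose candidates fail are deferred to the gap-stitching stage.
#'
#' @name expander
NULL

.vnorm <- function(v) sqrt(sum(v^2))

.angle_deg <- function(a, b) {
  na <- .vnorm(a); nb <- .vnorm(b)
  if (na == 0 || nb == 0) return(NA_real_)
  acos(pmin(1, pmax(-1, sum(a * b) / (na * nb)))) * 180 / pi
}

#' Project a point onto the isosurface (Newton steps)
#'
#' Iterates `x <- x - (psi(x) - iso) * grad / |grad|^2` until
#' `|psi - iso| < 1e-6 * psi_scale` (at most `max_iter` iterations).
#'
#' @param x n x 3 matrix (or length-3 vector) of start points.
#' @param field an `implicit_field`.
#' @param max_iter iteration cap per point.
#' @return list: `p` (n x 3 projected points), `normal` (n x 3 outward unit
#'   normals, i.e. `-grad psi / |grad psi|`), `converged` (logical).
#' @export
project_to_surface <- function(x, field, max_iter = 50) {
  x <- .as_pts(x)
  iso <- field$isovalue
  tol <- 1e-6 * field$psi_scale
  # surface gradients scale like psi_scale / node width; orders of
  # magnitude below that means a critical point, where Newton is undefined
  gfloor <- 1e-2 * field$psi_scale / field$width
  n <- nrow(x)
  active <- rep(TRUE, n)
  normal <- matrix(NA_real_, n, 3)
  lo <- field$c0 + 1e-9
  hi <- field$c0 + field$width - 1e-9
  for (it in seq_len(max_iter + 1)) {
    if (!any(active)) break
    xa <- x[active, , drop = FALSE]
    ev <- evaluate_field(field, xa)
    g2 <- rowSums(ev$grad^2)
    if (any(g2 < gfloor^2))
      stop("vanishing gradient during surface projection (critical point)")
    gl <- sqrt(g2)
    normal[active, ] <- -ev$grad / gl
    err <- ev$psi - iso
    done <- abs(err) < tol
    if (it > max_iter) break
    idx <- which(active)
    still <- idx[!done]
    active[idx[done]] <- FALSE
    if (length(still) == 0) next
    sel <- !done
    step <- -(err[sel] / g2[sel]) * ev$grad[sel, , drop = FALSE]
    # cap the Newton step to two node widths to avoid overshoot
    slen <- sqrt(rowSums(step^2))
    cap <- 2 * field$w
    over <- slen > cap
    if (any(over)) step[over, ] <- step[over, , drop = FALSE] * (cap / slen[over])
    xn <- x[still, , drop = FALSE] + step
    xn <- pmin(pmax(xn, matrix(lo, length(still), 3, byrow = TRUE)),
               matrix(hi, length(still), 3, byrow = TRUE))
    x[still, ] <- xn
  }
  list(p = x, normal = normal, converged = !active)
}

#' Radius of curvature from surface probes
#'
#' `r = min_i d_i / (2 sin(theta_i / 2))` over probe points `q_i` with
#' normals `n_qi`, where `d_i = |p - q_i|` and `theta_i` is the angle
#' between `n_p` and `n_qi`. Angles below `1e-4` rad contribute `r_max`
#' (flat limit); the result is clamped to `[r_min, r_max]`.
#'
#' @param p surface point (length 3).
#' @param n_p unit normal at `p`.
#' @param probes m x 3 matrix of probe surface points.
#' @param probe_normals m x 3 matrix of unit normals at the probes.
#' @param r_min,r_max clamping bounds (world length).
#' @return list with `r` and `clamped`.
#' @export
radius_of_curvature <- function(p, n_p, probes, probe_normals,
                                r_min = 1e-3, r_max = 1e3) {
  probes <- .as_pts(probes)
  probe_normals <- .as_pts(probe_normals)
  if (nrow(probes) == 0) stop("empty probe list")
  d <- sqrt(rowSums(sweep(probes, 2, as.numeric(p))^2))
  ct <- pmin(1, pmax(-1, probe_normals %*% as.numeric(n_p)))
  theta <- acos(ct)
  r_i <- ifelse(theta < 1e-4, r_max, d / (2 * sin(theta / 2)))
  r <- min(r_i)
  clamped <- r <= r_min || r >= r_max
  list(r = min(max(r, r_min), r_max), clamped = clamped)
}

# ---------------------------------------------------------------------------
# Growing mesh: mutable structure (environment) with directed half-edge
# bookkeeping. A triangle (a, b, c) is wound counter-clockwise seen from
# outside; a directed edge u->v is boundary when no face carries v->u.
# ---------------------------------------------------------------------------

.new_growing_mesh <- function(field, cap_v = 1024L, cap_f = 2048L) {
  M <- new.env(parent = emptyenv())
  M$field <- field
  M$V <- matrix(NA_real_, cap_v, 3)
  M$VN <- matrix(NA_real_, cap_v, 3)
  M$nv <- 0L
  M$F <- matrix(NA_integer_, cap_f, 3)
  M$nf <- 0L
  M$fcent <- matrix(NA_real_, cap_f, 3)
  M$flong <- rep(NA_real_, cap_f)
  M$fbound <- rep(FALSE, cap_f)
  M$he <- new.env(parent = emptyenv())   # "u,v" -> face id
  M$bout <- integer(cap_v)               # vertex -> boundary successor (0 none)
  M$bin <- integer(cap_v)
  M$queue <- matrix(NA_integer_, 4096L, 2)
  M$qhead <- 1L
  M$qtail <- 0L
  M$stats <- c(proj_fail = 0L, deferred = 0L, ears = 0L, grown = 0L,
               retries = 0L, defer_angle = 0L, defer_prox = 0L,
               defer_collapse = 0L, defer_geom = 0L)
  M$requeued <- new.env(parent = emptyenv())  # edge key -> times re-queued
  class(M) <- "growing_mesh"
  M
}

#' @export
print.growing_mesh <- function(x, ...) {
  cat(sprintf("growing_mesh: %d vertices, %d faces, %d queued boundary edges\n",
              x$nv, x$nf, max(0L, x$qtail - x$qhead + 1L)))
  invisible(x)
}

.gm_add_vertex <- function(M, pos, normal) {
  if (M$nv == nrow(M$V)) {
    M$V <- rbind(M$V, matrix(NA_real_, nrow(M$V), 3))
    M$VN <- rbind(M$VN, matrix(NA_real_, nrow(M$VN), 3))
    M$bout <- c(M$bout, integer(length(M$bout)))
    M$bin <- c(M$bin, integer(length(M$bin)))
  }
  M$nv <- M$nv + 1L
  M$V[M$nv, ] <- pos
  M$VN[M$nv, ] <- normal
  M$nv
}

.gm_push <- function(M, u, v) {
  if (M$qtail == nrow(M$queue))
    M$queue <- rbind(M$queue, matrix(NA_integer_, nrow(M$queue), 2))
  M$qtail <- M$qtail + 1L
  M$queue[M$qtail, ] <- c(u, v)
}

.he_key <- function(u, v) paste0(u, ",", v)

.gm_can_add_face <- function(M, a, b, c) {
  if (a == b || b == c || a == c) return("degenerate face")
  vs <- c(a, b, c)
  for (i in 1:3) {
    u <- vs[i]; v <- vs[i %% 3 + 1]
    if (!is.null(M$he[[.he_key(u, v)]])) return("duplicate directed edge")
  }
  TRUE
}

.gm_face_is_boundary <- function(M, f) {
  vs <- M$F[f, ]
  for (i in 1:3) {
    u <- vs[i]; v <- vs[i %% 3 + 1]
    if (is.null(M$he[[.he_key(v, u)]])) return(TRUE)
  }
  FALSE
}

.gm_add_face <- function(M, a, b, c) {
  ok <- .gm_can_add_face(M, a, b, c)
  if (!isTRUE(ok)) stop("cannot add face: ", ok)
  if (M$nf == nrow(M$F)) {
    M$F <- rbind(M$F, matrix(NA_integer_, nrow(M$F), 3))
    M$fcent <- rbind(M$fcent, matrix(NA_real_, nrow(M$fcent), 3))
    M$flong <- c(M$flong, rep(NA_real_, length(M$flong)))
    M$fbound <- c(M$fbound, rep(FALSE, length(M$fbound)))
  }
  M$nf <- M$nf + 1L
  f <- M$nf
  M$F[f, ] <- c(a, b, c)
  tv <- M$V[c(a, b, c), , drop = FALSE]
  M$fcent[f, ] <- colMeans(tv)
  M$flong[f] <- max(.vnorm(tv[1, ] - tv[2, ]), .vnorm(tv[2, ] - tv[3, ]),
                    .vnorm(tv[3, ] - tv[1, ]))
  vs <- c(a, b, c)
  touched <- integer(0)
  for (i in 1:3) {
    u <- vs[i]; v <- vs[i %% 3 + 1]
    M$he[[.he_key(u, v)]] <- f
    rev_f <- M$he[[.he_key(v, u)]]
    if (is.null(rev_f)) {
      M$bout[u] <- v
      M$bin[v] <- u
    } else {
      # the undirected edge just became interior
      if (M$bout[v] == u) M$bout[v] <- 0L
      if (M$bin[u] == v) M$bin[u] <- 0L
      touched <- c(touched, rev_f)
    }
  }
  M$fbound[f] <- .gm_face_is_boundary(M, f)
  for (tf in unique(touched)) M$fbound[tf] <- .gm_face_is_boundary(M, tf)
  f
}

# Exact triangle-triangle proximity test. All faces near the candidate are
# checked, not only the ones that still carry a boundary edge: a growing
# strip can otherwise corkscrew through regions whose faces have already
# become interior and never terminate.
.gm_proximity_ok <- function(M, tri, exclude_vertices) {
  if (M$nf == 0) return(TRUE)
  cand_long <- max(.vnorm(tri[1, ] - tri[2, ]), .vnorm(tri[2, ] - tri[3, ]),
                   .vnorm(tri[3, ] - tri[1, ]))
  cc <- colMeans(tri)
  sel <- seq_len(M$nf)
  thr <- pmax(M$flong[sel], cand_long) / 3
  d2 <- (M$fcent[sel, 1] - cc[1])^2 + (M$fcent[sel, 2] - cc[2])^2 +
    (M$fcent[sel, 3] - cc[3])^2
  reach <- thr + 0.6 * (M$flong[sel] + cand_long)
  near <- sel[d2 <= reach^2]
  if (length(near) == 0) return(TRUE)
  t1 <- as.numeric(t(tri))
  for (idx in seq_along(near)) {
    f <- near[idx]
    fv <- M$F[f, ]
    if (any(fv %in% exclude_vertices)) next
    t2 <- as.numeric(t(M$V[fv, , drop = FALSE]))
    if (cpp_tri_tri_dist(t1, t2) < max(M$flong[f], cand_long) / 3)
      return(FALSE)
  }
  TRUE
}


#' Seed the growing mesh with a hexagonal fan
#'
#' Projects the start point to the surface, probes the local radius of
#' curvature with a provisional tangent hexagon, rebuilds the hexagon with
#' circumradius `rho * r`, reprojects its vertices, and installs the six
#' triangles around the centre. The six outer edges are queued.
#'
#' @param field an `implicit_field`.
#' @param start world point near the surface.
#' @param rho edge-scale constant (edge length = `rho * r`).
#' @param r_min,r_max curvature-radius clamps; default to half / 100 times
#'   the field's node width.
#' @param h0 provisional hexagon radius used for the first curvature probe.
#' @param mesh optionally an existing `growing_mesh` to seed an additional
#'   component into.
#' @return A `growing_mesh`.
#' @export
seed_mesh <- function(field, start, rho = 0.15, r_min = NULL, r_max = NULL,
                      h0 = NULL, mesh = NULL) {
  if (is.null(r_min)) r_min <- 0.5 * field$w
  if (is.null(r_max)) r_max <- 100 * field$w
  if (is.null(h0)) h0 <- field$w
  pr <- project_to_surface(start, field)
  if (!all(pr$converged)) stop("seed point failed to project onto the surface")
  p <- pr$p[1, ]
  n_p <- pr$normal[1, ]
  e1 <- if (abs(n_p[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * n_p) * n_p
  e1 <- e1 / .vnorm(e1)
  e2 <- c(n_p[2] * e1[3] - n_p[3] * e1[2],
          n_p[3] * e1[1] - n_p[1] * e1[3],
          n_p[1] * e1[2] - n_p[2] * e1[1])
  hexa <- function(rad) {
    ang <- (0:5) * pi / 3
    sweep(outer(cos(ang), e1 * rad) + outer(sin(ang), e2 * rad), 2, p, "+")
  }
  probe <- project_to_surface(hexa(h0), field)
  if (!all(probe$converged)) stop("seed hexagon failed to project onto the surface")
  rc <- radius_of_curvature(p, n_p, probe$p, probe$normal, r_min, r_max)
  edge_min <- field$w
  L <- max(rho * rc$r, edge_min)
  # in flat regions r is clamped at r_max and the hexagon may overshoot the
  # surface entirely; shrink geometrically until all vertices project close
  # by, but never below one basis-node width (finer hexagons carry no
  # surface information and would start the whole mesh at a bogus scale)
  ring <- NULL
  for (try in 1:10) {
    cand <- tryCatch(project_to_surface(hexa(L), field), error = function(e) NULL)
    if (!is.null(cand) && all(cand$converged)) {
      dd <- sqrt(rowSums(sweep(cand$p, 2, p)^2))
      tilt <- cand$normal %*% n_p
      el <- sqrt(rowSums((cand$p - cand$p[c(2:6, 1), , drop = FALSE])^2))
      if (all(dd <= 1.8 * L) && all(dd >= 0.3 * L) && all(tilt > 0.25) &&
          all(el >= 0.6 * L) && all(el <= 1.7 * L)) {
        ring <- cand
        break
      }
    }
    if (L <= edge_min) break
    L <- max(L / 2, edge_min)
  }
  if (is.null(ring)) stop("seed hexagon failed to project onto the surface")
  M <- if (is.null(mesh)) .new_growing_mesh(field) else mesh
  M$rho <- rho; M$r_min <- r_min; M$r_max <- r_max
  # triangles smaller than one basis-node width cannot resolve additional
  # surface detail; the floor also stops ripple noise in the curvature
  # probes from shrinking the mesh indefinitely
  M$edge_min <- edge_min
  vc <- .gm_add_vertex(M, p, n_p)
  vids <- vapply(1:6, function(i)
    .gm_add_vertex(M, ring$p[i, ], ring$normal[i, ]), integer(1))
  # wind triangles counter-clockwise around the outward normal
  ori <- ring$p[1, ] - p
  ori2 <- ring$p[2, ] - p
  cr <- c(ori[2] * ori2[3] - ori[3] * ori2[2],
          ori[3] * ori2[1] - ori[1] * ori2[3],
          ori[1] * ori2[2] - ori[2] * ori2[1])
  order6 <- if (sum(cr * n_p) >= 0) 1:6 else 6:1
  vids <- vids[order6]
  for (i in 1:6) {
    a <- vids[i]; b <- vids[i %% 6 + 1]
    .gm_add_face(M, vc, a, b)
    .gm_push(M, a, b)
  }
  M
}

#' One expansion step
#'
#' Pops a boundary edge and attempts the ear rule or a new-vertex triangle
#' as described in [expander]. Mutates and returns the mesh.
#'
#' @param M a `growing_mesh` (from [seed_mesh()]).
#' @param field the `implicit_field`.
#' @param rho edge-scale constant.
#' @param ear_limit wedge-angle threshold (degrees) for the ear rule.
#' @param grow whether new-vertex candidates may be created; `FALSE`
#'   restricts the step to ear closure (used by the cleanup passes).
#' @return The mesh, invisibly.
#' @export
expand_step <- function(M, field, rho = M$rho, ear_limit = 70, grow = TRUE) {
  repeat {
    if (M$qhead > M$qtail) return(invisible(M))
    u <- M$queue[M$qhead, 1]; v <- M$queue[M$qhead, 2]
    M$qhead <- M$qhead + 1L
    if (M$bout[u] == v) break   # still a boundary edge; otherwise stale
  }
  pu <- M$V[u, ]; pv <- M$V[v, ]
  f <- M$he[[.he_key(u, v)]]
  wv <- setdiff(M$F[f, ], c(u, v))[1]
  # --- ear rule: adjacent boundary edges meeting at < 70 degrees ---------
  x <- M$bout[v]
  t <- M$bin[u]
  # an ear whose vertex set equals the owning face would double-cover it
  ang_v <- if (x != 0L && x != u && x != wv)
    .angle_deg(pu - pv, M$V[x, ] - pv) else Inf
  ang_u <- if (t != 0L && t != v && t != wv)
    .angle_deg(pv - pu, M$V[t, ] - pu) else Inf
  for (side in order(c(ang_v, ang_u))) {
    ang <- c(ang_v, ang_u)[side]
    if (!is.finite(ang) || ang >= ear_limit) next
    if (side == 1) { tri_ids <- c(x, v, u); enq <- c(u, x) }
    else           { tri_ids <- c(v, u, t); enq <- c(t, v) }
    if (!isTRUE(.gm_can_add_face(M, tri_ids[1], tri_ids[2], tri_ids[3]))) next
    tv <- M$V[tri_ids, , drop = FALSE]
    g <- .tri_alpha_area_normal(tv[1, ], tv[2, ], tv[3, ])
    if (is.null(g)) next
    closes <- !is.null(M$he[[.he_key(enq[2], enq[1])]])
    if (!closes) {
      # do not manufacture needles: thin notches are better closed by the
      # minimum-weight stitcher, which may reach across the gap instead
      if (g$alpha < 20) next
      # during the cleanup passes growth is over, so an ear cannot block a
      # front any more; across the seam the opposite bank is always within
      # the clearance, so the proximity test must not veto seam closure
      if (grow && !.gm_proximity_ok(M, tv, tri_ids)) next
    }
    .gm_add_face(M, tri_ids[1], tri_ids[2], tri_ids[3])
    if (M$bout[enq[1]] == enq[2]) .gm_push(M, enq[1], enq[2])
    M$stats["ears"] <- M$stats["ears"] + 1L
    return(invisible(M))
  }
  if (!grow) return(invisible(M))
  # --- new-vertex candidate ---------------------------------------------
  # a deferred edge goes back to the end of the queue a bounded number of
  # times: its surroundings keep changing (ears may become possible, blocking
  # fronts may be consumed), and without re-examination single rejections
  # snowball into ragged fronts; after the allowance it waits for stitching
  defer <- function(reason = NULL) {
    M$stats["deferred"] <- M$stats["deferred"] + 1L
    if (!is.null(reason))
      M$stats[reason] <- M$stats[reason] + 1L
    key <- .he_key(u, v)
    cnt <- M$requeued[[key]]
    if (is.null(cnt)) cnt <- 0L
    if (cnt < 2L) {
      M$requeued[[key]] <- cnt + 1L
      .gm_push(M, u, v)
    }
    invisible(M)
  }
  pw <- M$V[wv, ]
  m <- (pu + pv) / 2
  e <- pv - pu
  elen <- .vnorm(e)
  # growing from a sub-resolution edge would lock the mesh at a scale the
  # field cannot support; leave such edges to the stitcher
  if (elen < 0.5 * M$edge_min) return(defer("defer_geom"))
  dir <- (m - pw) - (sum((m - pw) * e) / elen^2) * e
  dl <- .vnorm(dir)
  if (dl < 1e-12) return(defer("defer_geom"))
  dir <- dir / dl
  # equilateral probe position, projected to the surface to estimate r
  p0 <- m + dir * (elen * sqrt(3) / 2)
  ps <- tryCatch(project_to_surface(p0, field), error = function(e) NULL)
  if (is.null(ps) || !all(ps$converged)) {
    M$stats["proj_fail"] <- M$stats["proj_fail"] + 1L
    return(defer())
  }
  rc <- radius_of_curvature(ps$p[1, ], ps$normal[1, ],
                            rbind(pu, pv), M$VN[c(u, v), , drop = FALSE],
                            M$r_min, M$r_max)
  L <- rho * rc$r
  # when the curvature radius asks for a larger triangle than the angle
  # window admits, take the largest admissible edge instead of failing:
  # the mesh then recovers toward rho * r at the window's maximal rate
  if (L > 1.44 * elen) L <- 1.44 * elen
  L <- max(L, M$edge_min)
  heights <- c(sqrt(max(L^2 - (elen / 2)^2, (0.05 * elen)^2)),
               elen * sqrt(3) / 2)   # retry: pull to the bisector
  for (attempt in seq_along(heights)) {
    p1 <- m + dir * heights[attempt]
    # base angles of the constructed in-plane triangle: the 50-70 degree
    # window constrains the edge-length ratio rho*r vs |uv| before the
    # final projection perturbs the vertex
    a_u <- .angle_deg(pv - pu, p1 - pu)
    a_v <- .angle_deg(pu - pv, p1 - pv)
    if (is.na(a_u) || is.na(a_v) || a_u < 50 || a_u > 70 || a_v < 50 ||
        a_v > 70) {
      if (attempt == 1) { M$stats["retries"] <- M$stats["retries"] + 1L; next }
      return(defer("defer_angle"))
    }
    # never leave a residual wedge under 20 degrees at either endpoint: it
    # would force a sliver on whoever closes it; deferring lets a relaxed
    # ear close the whole wedge with a well-shaped triangle instead
    if (x != 0L && x != u) {
      rv <- .angle_deg(p1 - pv, M$V[x, ] - pv)
      if (!is.na(rv) && rv < 20) {
        if (attempt == 1) { M$stats["retries"] <- M$stats["retries"] + 1L; next }
        return(defer("defer_angle"))
      }
    }
    if (t != 0L && t != v) {
      ru <- .angle_deg(p1 - pu, M$V[t, ] - pu)
      if (!is.na(ru) && ru < 20) {
        if (attempt == 1) { M$stats["retries"] <- M$stats["retries"] + 1L; next }
        return(defer("defer_angle"))
      }
    }
    pr <- tryCatch(project_to_surface(p1, field), error = function(e) NULL)
    if (is.null(pr) || !all(pr$converged)) {
      M$stats["proj_fail"] <- M$stats["proj_fail"] + 1L
      return(defer())
    }
    p <- pr$p[1, ]
    # reject projections that collapse onto the base edge
    if (.vnorm(p - pu) < 0.2 * elen || .vnorm(p - pv) < 0.2 * elen) {
      if (attempt == 1) { M$stats["retries"] <- M$stats["retries"] + 1L; next }
      return(defer("defer_collapse"))
    }
    tri <- rbind(p, pv, pu)
    if (!.gm_proximity_ok(M, tri, c(u, v))) return(defer("defer_prox"))
    np <- .gm_add_vertex(M, p, pr$normal[1, ])
    .gm_add_face(M, v, u, np)
    .gm_push(M, u, np)
    .gm_push(M, np, v)
    M$stats["grown"] <- M$stats["grown"] + 1L
    return(invisible(M))
  }
  defer()
}

#' Run expansion until the queue empties
#'
#' After the main queue empties, cleanup passes sweep the remaining
#' boundary with the ear rule at progressively relaxed wedge thresholds
#' (90, 110, 130 degrees): closing a wedge with existing vertices is the
#' same local operation the gap stitcher would perform, and shrinking the
#' gaps this way leaves the minimum-weight triangulation only the genuinely
#' open regions.
#'
#' @param M a seeded `growing_mesh`.
#' @param field the `implicit_field`.
#' @param rho edge-scale constant.
#' @param max_triangles cap on the number of triangles; exceeding it raises
#'   an error of class `vesselmesh_cap_error` carrying the partial mesh.
#' @return The mesh, invisibly.
#' @export
expand_all <- function(M, field, rho = M$rho, max_triangles = 200000L) {
  .expand_queue(M, field, rho, max_triangles, ear_limit = 70, grow = TRUE)
  cleanup <- function() {
    for (limit in c(90, 110)) {
      # ear chains cascade through the in-queue pushes, so a few sweeps per
      # threshold suffice
      for (sweep in 1:3) {
        nf0 <- M$nf
        be <- boundary_edges(M)
        if (nrow(be) == 0) break
        for (r in seq_len(nrow(be))) .gm_push(M, be[r, 1], be[r, 2])
        .expand_queue(M, field, rho, max_triangles, ear_limit = limit,
                      grow = FALSE)
        if (M$nf == nf0) break
      }
    }
  }
  cleanup()
  invisible(M)
}

.expand_queue <- function(M, field, rho, max_triangles, ear_limit, grow) {
  while (M$qhead <= M$qtail) {
    if (M$nf >= max_triangles) {
      cond <- structure(class = c("vesselmesh_cap_error", "error", "condition"),
                        list(message = sprintf(
                          "triangle cap exceeded (%d); runaway growth", max_triangles),
                          call = sys.call(), mesh = M))
      stop(cond)
    }
    expand_step(M, field, rho, ear_limit = ear_limit, grow = grow)
  }
  invisible(M)
}

#' Extract the current triangle mesh from a growing mesh
#'
#' @param M a `growing_mesh`.
#' @return A [triangle_mesh()] with per-vertex outward normals.
#' @export
finalize_mesh <- function(M) {
  triangle_mesh(M$V[seq_len(M$nv), , drop = FALSE],
                M$F[seq_len(M$nf), , drop = FALSE],
                normals = M$VN[seq_len(M$nv), , drop = FALSE])
}

#' Current boundary (directed) edges of a growing mesh
#'
#' @param M a `growing_mesh`.
#' @return 2-column integer matrix of directed boundary edges `u -> v`.
#' @export
boundary_edges <- function(M) {
  vs <- which(M$bout[seq_len(M$nv)] != 0L)
  cbind(vs, M$bout[vs])
}
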