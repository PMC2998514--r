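# Shared fixture: R = 10 sphere field (depth 5) used across blocks.
.sph <- shape_sphere(c(0, 0, 0), 10)
.vol <- rasterize(.sph, spacing = c(1, 1, 1))
.cloud <- orient_normals(extract_points(.vol), .vol, k = 10)
.fld <- poisson_field(.cloud, depth = 5)

.seed_somewhere <- function(field, cloud, rho = 0.15, ...) {
  ctr <- colMeans(cloud$positions)
  d2 <- rowSums(sweep(cloud$positions, 2, ctr)^2)
  for (ci in order(d2)[floor(seq(1, nrow(cloud$positions), length.out = 20))]) {
    M <- tryCatch(seed_mesh(field, cloud$positions[ci, ], rho = rho, ...),
                  error = function(e) NULL)
    if (!is.null(M)) return(M)
  }
  stop("no seed found")
}

test_that("surface projection is a fixed point on the isosurface", {
  pr <- project_to_surface(c(0, 0, 10.4), .fld)
  expect_true(all(pr$converged))
  p <- pr$p[1, ]
  expect_lt(abs(evaluate_field(.fld, p)$psi - .fld$isovalue),
            1e-6 * .fld$psi_scale)
  # projecting again moves (essentially) nowhere
  pr2 <- project_to_surface(p, .fld)
  expect_lt(sqrt(sum((pr2$p[1, ] - p)^2)), 1e-4)
  # radial start at 1.15 R lands within 0.05 of the field's crossing radius
  pr3 <- project_to_surface(c(0, 11.5, 0), .fld)
  rs <- seq(8, 11.5, by = 0.001)
  ps <- evaluate_field(.fld, cbind(0, rs, 0))$psi - .fld$isovalue
  rc <- rs[which(diff(sign(ps)) != 0)[1]]
  expect_lt(abs(sqrt(sum(pr3$p[1, ]^2)) - rc), 0.05)
  # outward normal convention: -grad psi / |grad psi|
  ev <- evaluate_field(.fld, pr3$p)
  expect_equal(pr3$normal[1, ], -ev$grad[1, ] / sqrt(sum(ev$grad^2)),
               tolerance = 1e-9)
})

test_that("projection fails loudly at a vanishing gradient", {
  expect_error(project_to_surface(c(0, 0, 0), .fld), "gradient")
})

test_that("radius of curvature follows the chord/angle closed form", {
  # d = 1, theta = 60 degrees: r = 1 / (2 sin 30) = 1
  p <- c(0, 0, 0); n_p <- c(0, 0, 1)
  q <- c(1, 0, 0)
  n_q <- c(sin(pi / 3), 0, cos(pi / 3))
  rc <- radius_of_curvature(p, n_p, rbind(q), rbind(n_q),
                            r_min = 1e-3, r_max = 1e3)
  expect_equal(rc$r, 1, tolerance = 1e-12)
  expect_false(rc$clamped)

  # probes on a sphere of radius R recover exactly R for any central angle
  R <- 17
  for (ang in c(0.05, 0.3, 1.1)) {
    q <- R * c(sin(ang), 0, cos(ang))
    n_q <- c(sin(ang), 0, cos(ang))
    rc <- radius_of_curvature(c(0, 0, R), c(0, 0, 1), rbind(q), rbind(n_q),
                              r_min = 1e-3, r_max = 1e3)
    expect_equal(rc$r, R, tolerance = 1e-9)
  }

  # coplanar probes (zero normal deviation) clamp to r_max
  rc <- radius_of_curvature(c(0, 0, 0), c(0, 0, 1),
                            rbind(c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(0, 0, 1), c(0, 0, 1)),
                            r_min = 0.5, r_max = 40)
  expect_equal(rc$r, 40)
  expect_true(rc$clamped)
  expect_error(radius_of_curvature(c(0, 0, 0), c(0, 0, 1),
                                   matrix(numeric(0), ncol = 3),
                                   matrix(numeric(0), ncol = 3)), "probe")
})

test_that("the seed element is a hexagonal fan of six triangles", {
  M <- .seed_somewhere(.fld, .cloud)
  expect_equal(M$nv, 7)
  expect_equal(M$nf, 6)
  expect_equal(M$qtail - M$qhead + 1, 6)
  # all seed vertices on the isosurface
  psi <- evaluate_field(.fld, M$V[1:7, ])$psi
  expect_lt(max(abs(psi - .fld$isovalue)), 1e-5 * .fld$psi_scale)
})

test_that("seed edge length tracks rho times the curvature radius", {
  # seed away from the rasterization's axis plateaus, on a diagonal
  start <- 10 * c(1, 1, 1) / sqrt(3)
  vol20 <- rasterize(shape_sphere(c(0, 0, 0), 20))
  cl20 <- orient_normals(extract_points(vol20), vol20, k = 10)
  f20 <- poisson_field(cl20, depth = 6)
  M <- seed_mesh(f20, 20 * c(1, 1, 1) / sqrt(3), rho = 0.15)
  ring <- M$V[2:7, ]
  el <- sqrt(rowSums((ring - ring[c(2:6, 1), ])^2))
  expect_lt(max(abs(el - 0.15 * 20)) / (0.15 * 20), 0.35)
})

test_that("a flat field produces an equilateral seed with edge rho * r_max", {
  slab <- rasterize(shape_box(c(-12, -12, -4), c(12, 12, 4)))
  cls <- orient_normals(extract_points(slab), slab, k = 10)
  fs <- poisson_field(cls, depth = 5)
  rmax <- 8
  M <- seed_mesh(fs, c(0, 0, 4.5), rho = 0.15, r_min = 0.5, r_max = rmax)
  ring <- M$V[2:7, ]
  el <- sqrt(rowSums((ring - ring[c(2:6, 1), ])^2))
  expect_equal(mean(el), 0.15 * rmax, tolerance = 0.05)
  expect_lt(stats::sd(el) / mean(el), 1e-2)
})

test_that("expansion preserves the two-manifold-with-boundary invariant", {
  M <- .seed_somewhere(.fld, .cloud)
  for (i in 1:12) expand_step(M, .fld)
  m <- finalize_mesh(M)
  ed <- .mesh_edges(m$faces)
  cnt <- table(paste0(ed$a, ",", ed$b))
  expect_true(all(cnt <= 2))
  tp <- topology_report(m)
  expect_true(tp$manifold)
  expect_true(tp$oriented)
  # all vertices stay on the isosurface
  psi <- evaluate_field(.fld, m$vertices)$psi
  expect_lt(max(abs(psi - .fld$isovalue)), 1e-5 * .fld$psi_scale)
})

test_that("full expansion leaves only simple closed boundary loops", {
  M <- .seed_somewhere(.fld, .cloud)
  expand_all(M, .fld)
  m <- finalize_mesh(M)
  loops <- find_gap_loops(m)       # errors if any loop is non-simple
  n_bnd <- sum(vapply(loops, function(l) length(l$ids), integer(1)))
  expect_equal(topology_report(m)$boundary_edges, n_bnd)
})

test_that("the triangle cap raises an error with a usable partial mesh", {
  M <- .seed_somewhere(.fld, .cloud)
  err <- tryCatch(expand_all(M, .fld, max_triangles = 10),
                  vesselmesh_cap_error = function(e) e)
  expect_s3_class(err, "vesselmesh_cap_error")
  partial <- finalize_mesh(err$mesh)
  expect_true(topology_report(partial)$manifold)
})
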