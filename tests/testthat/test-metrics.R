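test_that("edge ratio follows the min/max edge definition", {
  eq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(edge_ratio(eq), 1, tolerance = 1e-12)
  needle <- rbind(c(0, 0, 0), c(1, 0, 0), c(cos(0.01), sin(0.01), 0))
  expect_lt(edge_ratio(needle), 0.011)   # sides 1, 1, ~0.01
  iso <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(edge_ratio(iso), 1 / sqrt(2), tolerance = 1e-12)
  # permutation invariance over vertex orderings
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(1, 3, 2))
  vals <- vapply(perms, function(p) edge_ratio(iso[p, ]), numeric(1))
  expect_equal(max(vals) - min(vals), 0)
})

test_that("edge-ratio histogram counts every triangle once", {
  m <- make_icosphere(1)
  rep <- edge_ratio_report(m)
  expect_equal(sum(rep$histogram), nrow(m$faces))
  expect_equal(rep$fraction_below(0.3) + rep$fraction_atleast(0.3), 1)
  expect_gte(rep$fraction_atleast(0.8), 0)
})

test_that("RMS curvature matches analytic values on canonical surfaces", {
  # densely meshed sphere: both curvatures 1/R, RMS = 1/R
  R <- 6
  sphm <- make_icosphere(3, radius = R)
  rc <- rms_curvature(sphm)
  expect_lt(abs(median(rc) - 1 / R) / (1 / R), 0.1)

  # plane: zero curvature at interior vertices
  pl <- make_plane_grid(8)
  rcp <- rms_curvature(pl)
  interior <- which(pl$vertices[, 1] > 1.5 & pl$vertices[, 1] < 6.5 &
                      pl$vertices[, 2] > 1.5 & pl$vertices[, 2] < 6.5)
  expect_lt(max(abs(rcp[interior])), 1e-6)

  # cylinder radius rho: curvatures (1/rho, 0), RMS = 1/(rho sqrt(2))
  rho <- 5
  cy <- make_cylinder_grid(radius = rho, height = 20, n_theta = 48, n_z = 24)
  rcy <- rms_curvature(cy)
  interior <- which(cy$vertices[, 3] > 5 & cy$vertices[, 3] < 15)
  expected <- 1 / (rho * sqrt(2))
  expect_lt(abs(median(rcy[interior]) - expected) / expected, 0.1)
})

test_that("surface distance is zero against itself and exact for offsets", {
  m <- make_icosphere(2)
  set.seed(1)
  d0 <- surface_distance(m, m, samples_per_triangle = 2)
  expect_equal(d0$max, 0, tolerance = 1e-9)
  expect_equal(d0$mean, 0, tolerance = 1e-9)

  # unit sphere mesh against an analytic unit sphere shifted by 1 along x:
  # the maximal sampled distance approaches 1
  set.seed(2)
  ref <- shape_sphere(c(1, 0, 0), 1)
  d1 <- surface_distance(m, ref, samples_per_triangle = 5,
                         n_reference_samples = 4000)
  expect_equal(d1$max, 1, tolerance = 0.05)
  expect_true(d1$mean <= d1$max && d1$rms <= d1$max)

  # regular icosahedron with circumradius 1 vs the unit sphere:
  # max distance = 1 - inradius = 0.2053
  ico <- make_icosahedron()
  set.seed(3)
  d2 <- surface_distance(ico, shape_sphere(c(0, 0, 0), 1),
                         samples_per_triangle = 60,
                         n_reference_samples = 4000)
  expect_equal(d2$max, 1 - 0.7946545, tolerance = 0.02 * 0.2053)
})

test_that("refining the sampling never decreases the measured maximum", {
  ico <- make_icosahedron()
  ref <- shape_sphere(c(0, 0, 0), 1)
  set.seed(4)
  d_lo <- surface_distance(ico, ref, samples_per_triangle = 2,
                           n_reference_samples = 500)
  set.seed(4)
  d_hi <- surface_distance(ico, ref, samples_per_triangle = 50,
                           n_reference_samples = 5000)
  expect_gte(d_hi$max + 1e-9, d_lo$max)
})

test_that("topology reports recover Euler characteristic and components", {
  s <- make_icosphere(1)
  tp <- topology_report(s)
  expect_equal(tp$euler, 2)
  expect_equal(tp$components, 1)
  expect_equal(tp$boundary_edges, 0)
  expect_true(tp$manifold)
  expect_true(tp$oriented)

  t <- make_torus_grid()
  expect_equal(topology_report(t)$euler, 0)

  # two disjoint closed spheres: euler 4, two components
  s2 <- make_icosphere(1, center = c(10, 0, 0))
  both <- triangle_mesh(rbind(s$vertices, s2$vertices),
                        rbind(s$faces, s2$faces + nrow(s$vertices)))
  tpb <- topology_report(both)
  expect_equal(tpb$euler, 4)
  expect_equal(tpb$components, 2)

  # open fan: boundary edges counted, still manifold
  ang <- (0:5) * pi / 3
  V <- rbind(c(0, 0, 0), cbind(cos(ang), sin(ang), 0))
  fan <- triangle_mesh(V, cbind(1, 2:7, c(3:7, 2)))
  tpf <- topology_report(fan)
  expect_equal(tpf$boundary_edges, 6)
  expect_equal(tpf$euler, 1)
  expect_true(tpf$manifold)
})
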