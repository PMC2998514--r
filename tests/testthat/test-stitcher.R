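test_that("weight triples follow closed forms for canonical triangles", {
  # equilateral, side 1, indices (1,2,3) of a 3-point loop
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  w <- weight_of(P, 1, 2, 3)
  expect_equal(w[1], 60, tolerance = 1e-9)
  expect_equal(w[3], sqrt(3) / 4, tolerance = 1e-12)
  expect_equal(w[2], 0)     # no fixed neighbours given

  # right isoceles with legs 1: minimal angle 45 degrees
  P2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(weight_of(P2, 1, 2, 3)[1], 45, tolerance = 1e-9)

  # a coplanar fixed neighbour contributes zero dihedral deviation
  nrm <- c(0, 0, -1)    # matches the (k, m, i) winding of the patch
  w3 <- weight_of(P, 1, 2, 3, fixed_normals = rbind(nrm))
  expect_equal(w3[2], 0, tolerance = 1e-9)
  # an orthogonal neighbour contributes 90 degrees
  w4 <- weight_of(P, 1, 2, 3, fixed_normals = rbind(c(1, 0, 0)))
  expect_equal(w4[2], 90, tolerance = 1e-9)

  # degenerate (collinear) triangles get the worst weight
  P5 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(weight_of(P5, 1, 2, 3), c(0, 180, 0))
})

test_that("the weight order prefers alpha, then beta, then area", {
  expect_equal(compare_weights(c(60, 10, 5), c(50, 0, 0)), -1L)
  expect_equal(compare_weights(c(50, 5, 9), c(50, 7, 1)), -1L)
  expect_equal(compare_weights(c(50, 7, 1), c(50, 5, 9)), 1L)
  expect_equal(compare_weights(c(42, 3, 7), c(42, 3, 7)), 0L)
})

test_that("weight accumulation keeps the worst angle and dihedral", {
  expect_equal(add_weights(c(60, 0, 1), c(45, 20, 2)), c(45, 20, 3))
  a <- c(60, 0, 5)
  expect_equal(add_weights(a, c(60, 0, 0)), a)
  # commutativity over random triples
  set.seed(2)
  for (i in 1:20) {
    x <- c(runif(1, 0, 60), runif(1, 0, 180), runif(1, 0, 10))
    y <- c(runif(1, 0, 60), runif(1, 0, 180), runif(1, 0, 10))
    expect_equal(add_weights(x, y), add_weights(y, x))
  }
})

test_that("loop identification returns simple cycles with adjacency", {
  closed <- make_icosphere(1)
  expect_equal(length(find_gap_loops(closed)), 0)

  # hexagonal fan: a single 6-edge loop
  ang <- (0:5) * pi / 3
  V <- rbind(c(0, 0, 0), cbind(cos(ang), sin(ang), 0))
  F <- cbind(1, 2:7, c(3:7, 2))
  fan <- triangle_mesh(V, F)
  loops <- find_gap_loops(fan)
  expect_equal(length(loops), 1)
  expect_equal(length(loops[[1]]$ids), 6)
  expect_setequal(loops[[1]]$ids, 2:7)
  expect_equal(nrow(loops[[1]]$edge_normal), 6)

  # a bowtie boundary (two fans sharing a vertex) is rejected by name
  V2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  F2 <- rbind(c(1, 2, 3), c(1, 4, 5))
  expect_error(find_gap_loops(triangle_mesh(V2, F2)), "vertex 1")
})

test_that("the base case and the square tie-break behave as specified", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0))
  res <- triangulate_loop(P)
  expect_equal(res$triangles, matrix(c(1L, 2L, 3L), 1))
  expect_equal(res$weight[1], weight_of(P, 1, 2, 3)[1])

  # planar unit square: both diagonals tie at alpha = 45; the index-order
  # tie-break picks the split vertex m = 2, i.e. the diagonal (2, 4)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  res2 <- triangulate_loop(sq)
  expect_equal(nrow(res2$triangles), 2)
  uses_24 <- apply(res2$triangles, 1, function(r) all(c(2, 4) %in% r))
  expect_true(all(uses_24))
  expect_equal(res2$weight[1], 45, tolerance = 1e-9)
})

test_that("any loop triangulation covers every edge once with n-2 faces", {
  set.seed(31)
  ok_counts <- ok_edges <- ok_range <- TRUE
  for (rep in 1:10) {
    n <- sample(5:14, 1)
    lp <- random_loop(n)
    res <- triangulate_loop(lp)
    ok_counts <- ok_counts && nrow(res$triangles) == n - 2
    # every loop edge (i, i+1) and the closing edge appears in some triangle
    for (i in seq_len(n)) {
      j <- i %% n + 1
      hit <- apply(res$triangles, 1, function(r) i %in% r && j %in% r)
      ok_edges <- ok_edges && any(hit)
    }
    ok_range <- ok_range && all(res$triangles >= 1 & res$triangles <= n)
  }
  expect_true(ok_counts)
  expect_true(ok_edges)
  expect_true(ok_range)
})

test_that("the DP weight equals exhaustive enumeration on random loops", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(4:11, 1)
    lp <- random_loop(n)
    dp <- triangulate_loop(lp)
    oracle <- oracle_min_triangulation(lp$positions, lp$edge_normal)
    expect_equal(compare_weights(dp$weight, oracle), 0L,
                 label = sprintf("rep %d (n = %d)", rep, n))
  }
})

test_that("patch subdivision refines oversized faces and keeps manifoldness", {
  # tetrahedron with all faces treated as patch: every edge is splittable
  V <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  F <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))
  tet <- triangle_mesh(V, F)
  out <- subdivide_patch(tet, 1:4, threshold = 0.4)
  expect_gt(nrow(out$faces), 4)
  tp <- topology_report(out)
  expect_true(tp$manifold)
  expect_equal(tp$euler, 2)
  expect_equal(tp$boundary_edges, 0)
  # already at density: unchanged
  out2 <- subdivide_patch(tet, 1:4, threshold = 10)
  expect_equal(nrow(out2$faces), 4)
})

test_that("stitching closes a mesh to the prescribed Euler characteristic", {
  sph <- shape_sphere(c(0, 0, 0), 8)
  vol <- rasterize(sph)
  cl <- orient_normals(extract_points(vol), vol, k = 10)
  fld <- poisson_field(cl, depth = 5)
  ctr <- colMeans(cl$positions)
  d2 <- rowSums(sweep(cl$positions, 2, ctr)^2)
  M <- NULL
  for (ci in order(d2)[floor(seq(1, nrow(cl$positions), length.out = 20))]) {
    M <- tryCatch(seed_mesh(fld, cl$positions[ci, ], rho = 0.15),
                  error = function(e) NULL)
    if (!is.null(M)) break
  }
  expand_all(M, fld)
  open_mesh <- finalize_mesh(M)
  closed <- stitch_gaps(open_mesh, fld, target_euler = 2L)
  tp <- topology_report(closed)
  expect_equal(tp$euler, 2)
  expect_equal(tp$boundary_edges, 0)
  expect_true(tp$manifold)
  expect_true(tp$oriented)
})
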