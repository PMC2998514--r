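# Shared fixture: a small rasterized sphere and its solved field.
sph10 <- shape_sphere(c(0, 0, 0), 10)
vol10 <- rasterize(sph10, spacing = c(1, 1, 1))
cloud10 <- orient_normals(extract_points(vol10), vol10, k = 10)
field10 <- poisson_field(cloud10, depth = 5)

test_that("octree refines one path per isolated sample", {
  one <- list(positions = matrix(c(1, 2, 3), 1))
  oc <- build_octree(one, d = 4)
  expect_equal(nrow(oc$nodes), 5)             # root + one node per depth 1..4
  expect_equal(sum(oc$nodes$is_leaf), 1)
  expect_equal(oc$nodes$depth[oc$nodes$is_leaf], 4)

  two <- list(positions = rbind(c(-9, 0, 0), c(9, 0, 0)))
  oc2 <- build_octree(two, d = 5)
  leaves <- oc2$nodes[oc2$nodes$depth == 5, ]
  expect_equal(nrow(leaves), 2)
  expect_false(all(leaves$ix[1] == leaves$ix[2]))
  ids <- leaf_for_point(oc2, two$positions)
  expect_false(any(is.na(ids)))
  expect_equal(length(unique(ids)), 2)
})

test_that("every sphere sample lies in a depth-d leaf", {
  oc <- build_octree(cloud10, d = 5)
  ids <- leaf_for_point(oc, cloud10$positions)
  expect_false(any(is.na(ids)))
  leaves <- oc$nodes[match(ids, oc$nodes$id), ]
  # containment: each sample within the half-width box of its leaf
  expect_true(all(abs(cloud10$positions[, 1] - leaves$cx) <= leaves$width / 2 + 1e-9))
  expect_true(all(abs(cloud10$positions[, 2] - leaves$cy) <= leaves$width / 2 + 1e-9))
  expect_true(all(abs(cloud10$positions[, 3] - leaves$cz) <= leaves$width / 2 + 1e-9))
})

test_that("node basis is centred, compactly supported and unit-integral", {
  node <- list(center = c(1, -2, 0.5), width = 2)
  expect_gt(basis_value(node, node$center), 0)
  # maximal at the centre
  off <- basis_value(node, node$center + c(0.3, 0, 0))
  expect_lt(off, basis_value(node, node$center))
  # zero outside the 1.5 w box
  expect_equal(basis_value(node, node$center + c(3.01, 0, 0)), 0)
  expect_equal(basis_value(node, node$center + c(2, 2, 2) * 1.51), 0)
  # quadrature: integral over the support is 1
  gs <- seq(-1.5, 1.5, length.out = 61) * node$width
  h <- gs[2] - gs[1]
  pts <- as.matrix(expand.grid(x = gs, y = gs, z = gs))
  pts <- sweep(pts, 2, node$center, "+")
  integral <- sum(basis_value(node, pts)) * h^3
  expect_equal(integral, 1, tolerance = 1e-3)
})

test_that("trilinear splatting is exact at node centres and conserves mass", {
  P <- rbind(c(-4, 0, 0), c(4, 0, 0))
  N <- rbind(c(0, 0, 1), c(1, 0, 0))
  oc <- build_octree(list(positions = P), d = 4)
  # craft one sample exactly at a node centre
  ctr_node <- oc$c0 + (c(5, 8, 8) + 0.5) * oc$w
  cl <- list(positions = rbind(ctr_node, P[2, ]), normals = N)
  vf <- splat_vector_field(cl, oc)
  idx <- 5 + oc$n * 8 + oc$n^2 * 8 + 1
  expect_equal(vf$Vz[idx], 1, tolerance = 1e-9)   # full weight on that node
  # conservation: total splatted vector equals the sum of normals
  expect_equal(c(sum(vf$Vx), sum(vf$Vy), sum(vf$Vz)), colSums(N),
               tolerance = 1e-9)
  # midpoint between two node centres: weight 0.5/0.5 along that axis
  mid <- ctr_node + c(oc$w / 2, 0, 0)
  vf2 <- splat_vector_field(list(positions = rbind(mid, P[2, ]), normals = N),
                            oc)
  expect_equal(vf2$Vz[idx], 0.5, tolerance = 1e-9)
  expect_equal(vf2$Vz[idx + 1], 0.5, tolerance = 1e-9)
})

test_that("zero vector field solves to a constant (zero) indicator", {
  oc <- build_octree(cloud10, d = 4)
  vf <- list(Vx = array(0, rep(oc$n, 3)), Vy = array(0, rep(oc$n, 3)),
             Vz = array(0, rep(oc$n, 3)))
  coef <- solve_poisson(oc, vf)
  expect_equal(max(abs(coef)), 0)
})

test_that("indicator separates inside from outside on the sphere", {
  psi_centre <- evaluate_field(field10, c(0, 0, 0))$psi
  corner <- field10$c0 + 0.03 * field10$width
  psi_corner <- evaluate_field(field10, corner)$psi
  expect_gt(psi_centre, field10$isovalue)
  expect_lt(psi_corner, field10$isovalue)

  # >= 99% of probes 2 voxels inside/outside are classified correctly
  set.seed(3)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  psi_in <- evaluate_field(field10, dirs * 8)$psi
  psi_out <- evaluate_field(field10, dirs * 11.8)$psi
  expect_gte(mean(psi_in > field10$isovalue), 0.99)
  expect_gte(mean(psi_out < field10$isovalue), 0.99)
})

test_that("flipping all normals negates the solution", {
  flipped <- cloud10
  flipped$normals <- -flipped$normals
  f2 <- poisson_field(flipped, depth = 5)
  set.seed(5)
  q <- matrix(runif(60, -7, 7), ncol = 3)
  a <- evaluate_field(field10, q)$psi - field10$isovalue
  b <- evaluate_field(f2, q)$psi - f2$isovalue
  expect_equal(a, -b, tolerance = 1e-6 * field10$psi_scale)
})

test_that("analytic gradient matches central differences near the surface", {
  set.seed(9)
  dirs <- matrix(rnorm(150), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  p <- dirs * runif(50, 9, 10.8)
  ev <- evaluate_field(field10, p)
  h <- 1e-4
  num <- sapply(1:3, function(a) {
    dp <- matrix(0, nrow(p), 3); dp[, a] <- h
    (evaluate_field(field10, p + dp)$psi -
       evaluate_field(field10, p - dp)$psi) / (2 * h)
  })
  rel <- sqrt(rowSums((num - ev$grad)^2)) / sqrt(rowSums(ev$grad^2))
  expect_lt(max(rel), 1e-3)
})

test_that("the iso-level crossing sits within half a voxel of the radius", {
  set.seed(13)
  dirs <- matrix(rnorm(120), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  crossing <- vapply(seq_len(nrow(dirs)), function(i) {
    rs <- seq(7, 11.6, by = 0.01)
    ps <- evaluate_field(field10, outer(rs, dirs[i, ]))$psi - field10$isovalue
    rs[which(diff(sign(ps)) != 0)[1]]
  }, numeric(1))
  expect_lt(mean(abs(crossing - 10)), 0.5)
})

test_that("the selected isovalue is the mean indicator over the samples", {
  psi_s <- evaluate_field(field10, cloud10$positions)$psi
  expect_equal(field10$isovalue, mean(psi_s), tolerance = 1e-12)
  expect_equal(select_isovalue(field10, cloud10), field10$isovalue,
               tolerance = 1e-12)
})

test_that("translating the cloud translates the level set", {
  shift <- c(1.6, -2.3, 0.8)
  moved <- cloud10
  moved$positions <- sweep(moved$positions, 2, shift, "+")
  f2 <- poisson_field(moved, depth = 5)
  set.seed(21)
  dirs <- matrix(rnorm(60), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cross_of <- function(fld, origin) {
    vapply(seq_len(nrow(dirs)), function(i) {
      rs <- seq(7, 11.5, by = 0.01)
      pts <- sweep(outer(rs, dirs[i, ]), 2, origin, "+")
      ps <- evaluate_field(fld, pts)$psi - fld$isovalue
      rs[which(diff(sign(ps)) != 0)[1]]
    }, numeric(1))
  }
  r1 <- cross_of(field10, c(0, 0, 0))
  r2 <- cross_of(f2, shift)
  expect_lt(mean(abs(r1 - r2), na.rm = TRUE), 0.05)
})

test_that("points outside the octree bounds are rejected", {
  expect_error(evaluate_field(field10, field10$c0 + field10$width + 1),
               "outside")
  expect_error(splat_vector_field(
    list(positions = matrix(field10$c0 - 5, 1), normals = matrix(1, 1, 3)),
    field10$octree), "outside")
})
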