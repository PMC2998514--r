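test_that("covariance normal recovers the out-of-plane direction", {
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  n <- covariance_normal(c(0, 0, 0), nb)
  expect_equal(abs(n[3]), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(n^2)), 1, tolerance = 1e-9)

  # spherical cap: normal within 5 degrees of the radial direction
  set.seed(42)
  R <- 10
  p <- c(0, 0, R)
  th <- runif(12, 0, 2 * pi)
  cap <- runif(12, 0, 0.15)
  nb <- cbind(R * sin(cap) * cos(th), R * sin(cap) * sin(th), R * cos(cap))
  n <- covariance_normal(p, nb)
  ang <- acos(min(1, abs(sum(n * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang, 5)

  expect_error(covariance_normal(c(0, 0, 0),
                                 cbind(1:5, 0, 0)), "collinear")
  expect_error(covariance_normal(c(0, 0, 0), rbind(c(1, 0, 0), c(0, 1, 0))),
               "3 neighbours")
})

test_that("knn matches the brute-force oracle and excludes the query", {
  set.seed(7)
  P <- matrix(rnorm(900), ncol = 3)
  k <- 10
  nn <- knn(P, k)
  oracle <- brute_knn(P, k)
  # compare neighbour distances per row (ties may order differently)
  max_dev <- 0
  self_hit <- FALSE
  for (i in seq_len(nrow(P))) {
    di <- sqrt(colSums((t(P) - P[i, ])^2))
    max_dev <- max(max_dev, max(abs(sort(di[nn[i, ]]) - sort(di[oracle[i, ]]))))
    self_hit <- self_hit || (i %in% nn[i, ])
  }
  expect_lt(max_dev, 1e-12)
  expect_false(self_hit)
  # coincident duplicate points remain eligible as each other's neighbour
  P2 <- rbind(c(0, 0, 0), c(0, 0, 0), c(5, 0, 0), c(9, 0, 0))
  nn2 <- knn(P2, 1)
  expect_equal(nn2[1, 1], 2L)
  expect_equal(nn2[2, 1], 1L)
  expect_error(knn(P2, 4), "more than k")
})

test_that("one-dimensional neighbour example", {
  P <- cbind(c(0, 1, 2, 10), 0, 0)
  nn <- knn(P, 2)
  expect_setequal(nn[1, ], c(2L, 3L))
})

test_that("oriented normals point into the object", {
  vol <- rasterize(shape_sphere(c(0, 0, 0), 8))
  pts <- extract_points(vol)
  cloud <- orient_normals(pts, vol, k = 10)
  expect_equal(sqrt(rowSums(cloud$normals^2)), rep(1, nrow(cloud$normals)),
               tolerance = 1e-9)
  rad <- cloud$positions / sqrt(rowSums(cloud$positions^2))
  inward_frac <- mean(rowSums(cloud$normals * rad) < 0)
  expect_gte(inward_frac, 0.99)
  # orientation consistency with the source voxel direction
  vox <- voxel_world(vol, cloud$source_voxel)
  dots <- rowSums(cloud$normals * (vox - cloud$positions))
  expect_gte(mean(dots >= 0), 0.99)
})

test_that("normals on a flat slab face equal the true inward normal", {
  vol <- rasterize(shape_box(c(-8, -8, -3), c(8, 8, 3)))
  pts <- extract_points(vol)
  cloud <- orient_normals(pts, vol, k = 10)
  # top-face samples away from the rim: inward normal is exactly (0,0,-1)
  top <- which(abs(pts$z - max(pts$z)) < 1e-9 & abs(pts$x) < 5 & abs(pts$y) < 5)
  expect_gt(length(top), 10)
  ang <- acos(pmin(1, -cloud$normals[top, 3])) * 180 / pi
  expect_lt(max(ang), 1e-4)
})

test_that("normals are equivariant under rotation and translation", {
  set.seed(11)
  th <- runif(40, 0, 2 * pi)
  z <- runif(40, -2, 2)
  P <- cbind(4 * cos(th), 4 * sin(th), z)   # cylinder wall samples
  k <- 8
  nn <- knn(P, k)
  base <- t(vapply(seq_len(nrow(P)), function(i)
    covariance_normal(P[i, ], P[nn[i, ], ]), numeric(3)))
  # translation leaves normals unchanged
  P_t <- sweep(P, 2, c(3, -7, 2), "+")
  nt <- t(vapply(seq_len(nrow(P)), function(i)
    covariance_normal(P_t[i, ], P_t[nn[i, ], ]), numeric(3)))
  expect_lt(max(1 - abs(rowSums(base * nt))), 1e-6)
  # rotation rotates normals by the same matrix (up to sign)
  ang <- 0.7
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  P_r <- P %*% t(Rz)
  nr <- t(vapply(seq_len(nrow(P)), function(i)
    covariance_normal(P_r[i, ], P_r[nn[i, ], ]), numeric(3)))
  expect_lt(max(1 - abs(rowSums((base %*% t(Rz)) * nr))), 1e-6)
})
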