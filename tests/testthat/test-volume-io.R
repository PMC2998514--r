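test_that("binary volumes are binarized, padded and validated", {
  g <- array(0, c(2, 2, 2))
  g[] <- 255
  v <- binary_volume(g)
  expect_equal(dim(v$grid), c(4, 4, 4))       # one zero layer on every side
  expect_setequal(unique(as.vector(v$grid)), c(0L, 1L))
  expect_equal(sum(v$grid), 8)
  # origin shifted so world coordinates are unchanged by padding
  expect_equal(v$origin, c(-1, -1, -1))
  expect_error(binary_volume(array(0, c(3, 3, 3))), "empty")
  expect_error(binary_volume(array(1, c(3, 3)), ), "3D")
  expect_error(binary_volume(array(1, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
})

test_that("raw, MetaImage and NIfTI round trips preserve the grid", {
  g <- array(0L, c(6, 5, 4))
  g[2:4, 2:3, 2:3] <- 1L
  v <- binary_volume(g, spacing = c(0.7, 0.7, 1.2))
  for (ext in c("raw", "mhd", "mha", "nii")) {
    path <- file.path(tempdir(), paste0("vol_rt.", ext))
    save_volume(v, path)
    v2 <- load_volume(path)
    expect_identical(v2$grid, v$grid, label = ext)
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  }
  unlink(file.path(tempdir(), "vol_rt.*"))
})

test_that("loading rejects unreadable or empty input", {
  expect_error(load_volume(file.path(tempdir(), "nope.nii")), "not found")
  g <- array(0L, c(4, 4, 4))
  g[2, 2, 2] <- 1L
  v <- binary_volume(g)
  v$grid[] <- 0L
  path <- file.path(tempdir(), "empty.raw")
  con <- file(path, "wb")
  writeBin(as.raw(rep(0, 8)), con)
  close(con)
  jsonlite::write_json(list(dim = c(2, 2, 2), dtype = "uint8"),
                       paste0(path, ".json"), auto_unbox = FALSE)
  expect_error(load_volume(path), "empty")
})

test_that("rasterized sphere voxel count matches the lattice-point oracle", {
  R <- 10
  vol <- rasterize(shape_sphere(c(0, 0, 0), R), spacing = c(1, 1, 1))
  # independent oracle: enumerate lattice centres inside the ball
  xs <- -12:12
  grid <- expand.grid(x = xs, y = xs, z = xs)
  oracle <- sum(grid$x^2 + grid$y^2 + grid$z^2 < R^2)
  expect_equal(sum(vol$grid), oracle)
  expect_lt(abs(sum(vol$grid) - 4 / 3 * pi * R^3) / (4 / 3 * pi * R^3), 0.02)
})

test_that("tube cross sections match the 2D disc lattice count", {
  r <- 3
  tube <- shape_tube(c(0, 0, -10), c(0, 0, 10), r)
  vol <- rasterize(tube, spacing = c(1, 1, 1))
  xy <- expand.grid(x = -4:4, y = -4:4)
  disc <- sum(xy$x^2 + xy$y^2 < r^2)
  # interior slices (away from the end caps) all carry the same disc
  kz <- which(abs((0:(dim(vol$grid)[3] - 1)) + vol$origin[3]) <= 5)
  counts <- vapply(kz, function(k) sum(vol$grid[, , k]), integer(1))
  expect_true(all(counts == disc))
})

test_that("a sub-voxel sphere rasterizes to exactly one voxel", {
  vol <- rasterize(shape_sphere(c(0, 0, 0), 0.4), spacing = c(1, 1, 1))
  expect_equal(sum(vol$grid), 1)
})

test_that("rasterization is deterministic and save/load is bit exact", {
  shp <- shape_bifurcation(r = 3, length = 8)
  v1 <- rasterize(shp)
  v2 <- rasterize(shp)
  expect_identical(v1$grid, v2$grid)
  path <- file.path(tempdir(), "phantom_det.mha")
  save_volume(v1, path)
  expect_identical(load_volume(path)$grid, v1$grid)
  unlink(path)
})

test_that("voxel-complex Euler characteristic recovers genus", {
  g <- array(0L, c(5, 5, 5)); g[3, 3, 3] <- 1L
  expect_equal(volume_surface_euler(binary_volume(g)), 2L)
  expect_equal(volume_surface_euler(rasterize(shape_sphere(c(0, 0, 0), 6))), 2L)
  expect_equal(volume_surface_euler(
    rasterize(shape_torus(c(0, 0, 0), R_major = 8, r_minor = 3))), 0L)
  expect_equal(volume_surface_euler(
    rasterize(shape_bifurcation(r = 3, length = 10))), 2L)
})
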