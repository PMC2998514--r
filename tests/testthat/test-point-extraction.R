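test_that("boundary face counts match constellation enumeration", {
  v1 <- single_voxel_volume()
  expect_equal(nrow(find_boundary_faces(v1)), 6)

  g <- array(0L, c(6, 6, 6))
  g[3:4, 3:4, 3:4] <- 1L            # 2x2x2 block: 6 block faces x 4
  expect_equal(nrow(find_boundary_faces(binary_volume(g))), 24)

  g <- array(0L, c(3, 3, 7))
  g[2, 2, 2:6] <- 1L                # 1x1x5 line: 5*6 - 2*4 shared
  expect_equal(nrow(find_boundary_faces(binary_volume(g))), 22)
})

test_that("top-hat transform flags thin structures only", {
  g <- array(0L, c(3, 3, 7))
  g[2, 2, 2:6] <- 1L
  vol <- binary_volume(g)
  thin <- detect_thin_voxels(vol)
  expect_equal(sum(thin), 5)        # a 1-wide line is erased by opening
  expect_true(all(thin[vol$grid == 1L]))

  # a solid 5x5x5 cube is the union of 3x3x3 boxes, so opening reproduces
  # it exactly and no voxel is flagged
  g2 <- array(0L, c(9, 9, 9))
  g2[3:7, 3:7, 3:7] <- 1L
  expect_equal(sum(detect_thin_voxels(binary_volume(g2))), 0)

  # rasterized sphere with R >= 5 voxels: no thin voxels
  vol_s <- rasterize(shape_sphere(c(0, 0, 0), 6))
  expect_equal(sum(detect_thin_voxels(vol_s)), 0)
})

test_that("refined faces emit four subface samples on the interface", {
  v1 <- single_voxel_volume()
  pts <- extract_points(v1)
  expect_equal(nrow(pts), 24)            # 6 faces x 4 subfaces
  expect_true(all(pts$is_refined))

  # every sample lies exactly half a spacing from its object voxel centre
  # along the face axis, i.e. on the object/background interface
  ctr <- voxel_world(v1, cbind(pts$i, pts$j, pts$k))
  off <- cbind(pts$x, pts$y, pts$z) - ctr
  along <- off[cbind(seq_len(nrow(pts)), pts$axis)]
  expect_equal(abs(along), rep(0.5, nrow(pts)) * v1$spacing[pts$axis])
})

test_that("faces far from thin structures get a single centre sample", {
  g <- array(0L, c(14, 14, 14))
  g[3:12, 3:12, 3:12] <- 1L         # solid 10^3 cube: nothing is thin
  vol <- binary_volume(g)
  pts <- extract_points(vol)
  faces <- find_boundary_faces(vol)
  expect_false(any(pts$is_refined))
  expect_equal(nrow(pts), nrow(faces))
  # a +x face centre sits at voxel centre + spacing/2 along x
  sel <- which(pts$axis == 1 & pts$sign == 1)[1]
  ctr <- voxel_world(vol, cbind(pts$i[sel], pts$j[sel], pts$k[sel]))
  expect_equal(pts$x[sel], ctr[1] + 0.5)
  expect_equal(pts$y[sel], ctr[2])
  expect_equal(pts$z[sel], ctr[3])
})

test_that("sample count decomposes into refined and unrefined faces", {
  shp <- shape_tube(c(0, 0, -6), c(0, 0, 6), 1.4)  # thin tube: refinement
  vol <- rasterize(shp)
  faces <- find_boundary_faces(vol)
  pts <- extract_points(vol)
  n_ref_faces <- sum(pts$is_refined) / 4
  n_plain <- sum(!pts$is_refined)
  expect_equal(n_plain + n_ref_faces, nrow(faces))
  expect_gt(sum(pts$is_refined), 0)
  # interface property for every sample: voxels on either side are 1 and 0
  d <- dim(vol$grid)
  bg_i <- pts$i + ifelse(pts$axis == 1, pts$sign, 0L)
  bg_j <- pts$j + ifelse(pts$axis == 2, pts$sign, 0L)
  bg_k <- pts$k + ifelse(pts$axis == 3, pts$sign, 0L)
  expect_true(all(vol$grid[cbind(pts$i, pts$j, pts$k)] == 1L))
  expect_true(all(vol$grid[cbind(bg_i, bg_j, bg_k)] == 0L))
})
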