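test_that("voxelization reproduces analytic volumes of cube and sphere", {
  vm <- voxelize_mesh(box_mesh(10, 10, 10), 300)
  expect_lt(abs(sum(vm$labels == 3L) / 300^3 - 1), 0.01)
  s <- voxelize_mesh(sphere_mesh(r = 2), 300)
  vol <- sum(s$labels == 3L) * s$pitch_mm^3
  expect_lt(abs(vol / (4 / 3 * pi * 8) - 1), 0.02)
})

test_that("voxelization volume converges with resolution on the sphere", {
  errs <- sapply(c(150, 300, 600), function(res) {
    s <- voxelize_mesh(sphere_mesh(r = 2, n = 96), res)
    abs(sum(s$labels == 3L) * s$pitch_mm^3 / (4 / 3 * pi * 8) - 1)
  })
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1] + 1e-3)
})

test_that("open meshes are rejected", {
  ## planar patch: two triangles, not closed
  patch <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                         rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_false(is_watertight(patch))
  expect_error(voxelize_mesh(patch, 300), "watertight")
})

test_that("superficial shell is exactly 3 voxels deep at 300 px/cm", {
  lab <- array(0L, dim = c(24, 24, 16))
  lab[3:22, 3:22, 3:14] <- 3L
  m <- split_layers(voxel_model(lab, 10 / 300), 0.1)
  col <- m$labels[12, 12, ]
  ## top and bottom: 3 superficial voxels each, volumetric in between
  expect_identical(col[3:5], rep(2L, 3))
  expect_identical(col[12:14], rep(2L, 3))
  expect_identical(col[6:11], rep(3L, 6))
  ## lateral shells too
  row <- m$labels[, 12, 8]
  expect_identical(row[3:5], rep(2L, 3))
  expect_identical(row[6:19], rep(3L, 14))
  ## conservation: partition of the skeleton
  expect_equal(sum(m$labels %in% c(2L, 3L)), sum(lab == 3L))
  ## idempotent
  m2 <- split_layers(m, 0.1)
  expect_identical(m2$labels, m$labels)
})

test_that("plates thinner than twice the shell are entirely superficial", {
  lab <- array(0L, dim = c(12, 12, 9))
  lab[3:10, 3:10, 4:6] <- 3L  # 3 voxels thick = 100 um at 300 px/cm
  m <- split_layers(voxel_model(lab, 10 / 300), 0.1)
  expect_true(all(m$labels[lab == 3L] == 2L))
})

test_that("water layer adds exactly the requested slabs above a flat slab", {
  lab <- array(0L, dim = c(10, 10, 130))
  lab[, , 5:20] <- 3L
  m <- voxel_model(lab, 0.05)
  w <- add_water_layer(m, 100)
  d <- dim(w$labels)
  expect_equal(d[3], 130 + (100 - 4))  # padded so 100 slabs sit above the surface
  k_top <- min(which(apply(w$labels == 3L, 3, any)))
  expect_equal(k_top - 1, 100)
  expect_true(all(w$labels[, , 1:100] == 1L))
  expect_true(all(w$labels[, , (k_top):d[3]] != 1L))
  ## n = 0 leaves the model unchanged
  w0 <- add_water_layer(m, 0)
  expect_identical(w0$labels, m$labels)
})

test_that("flood-filled water reaches groove interiors but not sealed pores", {
  lab <- array(0L, dim = c(10, 10, 10))
  lab[, , 4:9] <- 3L
  lab[4:6, 4:6, 4:6] <- 0L       # open groove reaching the top of the slab
  lab[2:3, 2:3, 6:7] <- 0L       # sealed internal pore
  m <- add_water_layer(voxel_model(lab, 0.1), 2)
  ## groove interior is water (reached from the top by the flood fill)
  expect_true(all(m$labels[4:6, 4:6, 4:6] == 1L))
  ## sealed pore stays background
  expect_true(all(m$labels[2:3, 2:3, 6:7] == 0L))
})

test_that("rugosity index matches analytic fixtures", {
  xs <- seq(0, 4, by = 0.05)
  flat <- heightfield_mesh(xs, xs, matrix(0, length(xs), length(xs)), 1)
  expect_equal(rugosity_index(flat, list(x = c(0, 4), y = c(0, 4))), 1.0)
  hemi <- hemisphere_plate(r = 1, W = 4)
  expect_equal(rugosity_index(hemi, list(x = c(0, 4), y = c(0, 4))),
               (16 + pi) / 16, tolerance = 0.01)
  ## any height field projects to at least its planar area
  set.seed(2)
  zz <- matrix(stats::rnorm(41^2, sd = 0.2), 41, 41)
  zz <- (zz + t(zz)) / 2
  rough <- heightfield_mesh(seq(0, 4, by = 0.1), seq(0, 4, by = 0.1), zz, 3)
  expect_gte(rugosity_index(rough), 1)
  expect_error(rugosity_index(flat, list(x = c(-1, 3), y = c(0, 4))), "footprint")
})

test_that("rugosity is invariant under in-plane rotation of a symmetric fixture", {
  hemi <- hemisphere_plate(r = 1, W = 4, h = 0.025)
  r0 <- rugosity_index(hemi, list(x = c(1, 3), y = c(1, 3)))
  ## rotate the mesh 90 degrees about the window centre
  v <- hemi$vertices
  vr <- cbind(2 - (v[, 2] - 2), 2 + (v[, 1] - 2), v[, 3])
  hemir <- triangle_mesh(vr, hemi$faces)  # proper rotation preserves winding
  r90 <- rugosity_index(hemir, list(x = c(1, 3), y = c(1, 3)))
  expect_equal(r90, r0, tolerance = 0.002)
})

test_that("STL round trips preserve geometry", {
  m <- sphere_mesh(r = 1.5, n = 16)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, path)
  m2 <- read_stl(path)
  expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-5)
  expect_true(is_watertight(m2))
  ## ASCII STL reader
  ap <- withr::local_tempfile(fileext = ".stl")
  v <- m$vertices; f <- m$faces
  lines <- c("solid synthetic")
  for (t in seq_len(nrow(f))) {
    lines <- c(lines, " facet normal 0 0 0", "  outer loop",
               paste("   vertex", v[f[t, 1], 1], v[f[t, 1], 2], v[f[t, 1], 3]),
               paste("   vertex", v[f[t, 2], 1], v[f[t, 2], 2], v[f[t, 2], 3]),
               paste("   vertex", v[f[t, 3], 1], v[f[t, 3], 2], v[f[t, 3], 3]),
               "  endloop", " endfacet")
  }
  writeLines(c(lines, "endsolid synthetic"), ap)
  m3 <- read_stl(ap)
  expect_equal(mesh_volume(m3), mesh_volume(m), tolerance = 1e-5)
})
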