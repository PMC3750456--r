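test_that("a single voxel extracts to a closed surface of about one cell", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  mesh <- extract_surface(m, spacing = rep(1, 3), origin = c(0, 0, 0),
                          smooth_sigma_vox = 0)
  expect_true(is_watertight(mesh))
  expect_gt(mesh_volume(mesh), 0.2)   # octahedral core of the 1 mm^3 cell
  expect_lt(mesh_volume(mesh), 1.5)
})

test_that("a voxelised sphere extracts to the analytic volume within 2%", {
  h <- 0.5
  xs <- (seq_len(49) - 25) * h
  g <- expand.grid(x = xs, y = xs, z = xs)
  mask <- array(g$x^2 + g$y^2 + g$z^2 <= 100, c(49, 49, 49))
  mesh <- extract_surface(mask, spacing = rep(h, 3), origin = rep(xs[1], 3))
  expect_true(is_watertight(mesh))
  expect_lt(abs(mesh_volume(mesh) / 4188.79 - 1), 0.02)
  # and within 3% of the voxel-count volume
  expect_lt(abs(mesh_volume(mesh) / (sum(mask) * h^3) - 1), 0.03)
})

test_that("phantom cavity masks extract to watertight outward surfaces", {
  ph <- phantom_coarse()
  mesh <- extract_surface(ph$truth$cavity_masks$unaffected, ph$truth$spacing,
                          ph$truth$origin)
  expect_true(is_watertight(mesh))
  expect_gt(mesh_volume(mesh), 0)  # outward orientation
  expect_lt(abs(mesh_volume(mesh) / 1000 /
                ph$truth$volumes_ml[["unaffected"]] - 1), 0.03)
  expect_true(all(face_areas(mesh) > 1e-12))
  expect_error(extract_surface(array(FALSE, c(4, 4, 4)), rep(1, 3)), "empty")
})

test_that("vertex areas sum to the total surface area", {
  m <- icosphere(10, 2)
  expect_equal(sum(vertex_areas(m)), sum(face_areas(m)), tolerance = 1e-9)
})

test_that("mesh reflection preserves enclosed volume and orientation", {
  m <- icosphere(8, 2)
  pl <- plane3(c(1, 2, -1), c(3, 0, 1))
  r <- reflect_mesh(m, pl)
  expect_equal(mesh_volume(r), mesh_volume(m), tolerance = 1e-9)
  rr <- reflect_mesh(r, pl)
  expect_lt(max(abs(rr$vertices - m$vertices)), 1e-9)
  expect_identical(rr$faces, m$faces)
  # a vertex on the mirror plane is a fixed point
  v <- surface_mesh(rbind(c(3, 0, 1), c(4, 1, 1), c(3, 1, 5)),
                    matrix(c(1, 2, 3), 1))
  expect_equal(reflect_mesh(v, pl)$vertices[1, ], c(3, 0, 1))
})
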