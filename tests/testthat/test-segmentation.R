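random_orbit_mask <- function(dims, spacing) {
  m <- array(runif(prod(dims)) > 0.6, dims)
  structure(list(mask = m, spacing = spacing, origin = c(0, 0, 0),
                 side = "right", clipped = TRUE), class = "orbit_mask")
}

test_that("voxel-count volumetry equals an independent per-voxel loop", {
  set.seed(31)
  for (i in 1:50) {
    dims <- sample(3:12, 3, replace = TRUE)
    spacing <- runif(3, 0.2, 1.0)
    mask <- random_orbit_mask(dims, spacing)
    # brute force: iterate every voxel, count marked cells, scale once
    n_marked <- 0L
    for (v in seq_len(prod(dims)))
      if (mask$mask[v]) n_marked <- n_marked + 1L
    expect_identical(compute_volume(mask),
                     n_marked * ((spacing[1] * spacing[2]) * spacing[3]) / 1000)
  }
})

test_that("volumetry handles the worked example and the empty mask", {
  m <- array(FALSE, c(40, 40, 40))
  m[1:20, 1:20, 1:20] <- TRUE  # 8000 voxels
  om <- structure(list(mask = m, spacing = rep(0.5, 3), origin = c(0, 0, 0),
                       side = "left", clipped = TRUE), class = "orbit_mask")
  expect_equal(compute_volume(om), 1.0)
  om$mask[] <- FALSE
  expect_equal(compute_volume(om), 0.0)
  om$clipped <- FALSE
  expect_error(compute_volume(om), "clip")
})

test_that("bone thresholding is exact on a noiseless phantom and flags edge cases", {
  ph <- phantom_noiseless()
  bone <- threshold_bone(ph$preop, segmentation_params(300))
  expect_identical(unname(bone), unname(ph$truth$bone_mask_pre))
  expect_error(threshold_bone(volume_image(array(0, c(3, 3, 3)), rep(0.5, 3)),
                              segmentation_params(300)), "no bone")
  all_on <- threshold_bone(ph$preop, segmentation_params(-1e6))
  expect_true(all(all_on))
})

test_that("anterior clip plane contains L, M and the slice axis", {
  pl <- anterior_clip_plane(c(30, 40, 0), c(-2, 40, 0))
  expect_equal(pl$normal, c(0, 1, 0))
  expect_equal(plane_signed_distance(pl, c(5, 40, 7)), 0)
  # oblique L-M line: both points still on the plane
  L <- c(30, 42, 1); M <- c(-2, 38, 2)
  pl2 <- anterior_clip_plane(L, M)
  expect_lt(abs(plane_signed_distance(pl2, L)), 1e-9)
  expect_lt(abs(plane_signed_distance(pl2, M)), 1e-9)
  expect_gt(pl2$normal[2], 0)
  expect_error(anterior_clip_plane(c(0, 0, 0), c(0, 0, 1), c(0, 0, 1)),
               "parallel")
})

test_that("anterior clipping retains exactly the strictly posterior voxel centres", {
  dims <- c(9, 9, 9)
  mask <- structure(list(mask = array(TRUE, dims), spacing = rep(1, 3),
                         origin = c(36, 36, 36), side = "right",
                         clipped = FALSE), class = "orbit_mask")
  pl <- plane3(c(0, 1, 0), c(0, 40, 0))
  clipped <- clip_anterior(mask, pl)
  # brute-force half-space check on every voxel centre
  for (j in 1:9) {
    y <- 36 + (j - 1)
    expect_equal(unique(as.vector(clipped$mask[, j, ])), y < 40)
  }
  expect_true(clipped$clipped)
  # a fully posterior mask passes unchanged
  post <- mask
  post$origin <- c(0, 0, 0)
  expect_equal(sum(clip_anterior(post, pl)$mask), sum(post$mask))
  # clipping must never increase the volume
  expect_lte(sum(clipped$mask), sum(mask$mask))
})

test_that("cavity fill matches phantom truth and never leaks silently", {
  ph <- phantom_default()
  pre <- ph$preop
  p_ok <- segmentation_params(300, closing_radius_mm = 2.0)
  bone <- threshold_bone(pre, p_ok)
  # intact side: volume within 2% of generator truth
  cav <- segment_cavity(pre, bone, p_ok, side = ph$truth$unaffected_side,
                        landmarks = ph$landmarks, stop_plane = "landmarks")
  s <- side_landmarks(ph$landmarks, ph$truth$unaffected_side)
  cl <- clip_anterior(cav, anterior_clip_plane(s$L, s$M))
  expect_lt(abs(compute_volume(cl) / ph$truth$volumes_ml[["unaffected"]] - 1),
            0.02)
  # fractured side without closing: the fill escapes through the defect
  expect_error(
    segment_cavity(pre, bone, segmentation_params(300, closing_radius_mm = 0),
                   side = ph$truth$affected_side, landmarks = ph$landmarks,
                   stop_plane = "landmarks"),
    "leak")
  # with closing at least the defect gap it succeeds and shows enlargement
  cav_aff <- segment_cavity(pre, bone, p_ok, side = ph$truth$affected_side,
                            landmarks = ph$landmarks, stop_plane = "landmarks")
  sa <- side_landmarks(ph$landmarks, ph$truth$affected_side)
  cl_aff <- clip_anterior(cav_aff, anterior_clip_plane(sa$L, sa$M))
  expect_gt(compute_volume(cl_aff), compute_volume(cl))
})

test_that("per-slice subvolumes partition the total volume exactly", {
  ph <- phantom_coarse()
  pre <- ph$preop
  p <- segmentation_params(300, closing_radius_mm = 2.0)
  cav <- segment_cavity(pre, threshold_bone(pre, p), p,
                        side = ph$truth$unaffected_side,
                        landmarks = ph$landmarks, stop_plane = "landmarks")
  s <- side_landmarks(ph$landmarks, ph$truth$unaffected_side)
  cl <- clip_anterior(cav, anterior_clip_plane(s$L, s$M))
  prof <- per_slice_profile(cl)
  expect_identical(sum(prof$subvolume_ml), compute_volume(cl))
  expect_equal(prof$area_mm2, prof$n_voxels * prod(cl$spacing[1:2]))
  # convex cavity: occupied slice areas rise then fall along the height axis
  occ <- prof$n_voxels[prof$n_voxels > 0]
  peak <- which.max(occ)
  expect_true(all(diff(occ[seq_len(peak)]) >= 0))
  expect_true(all(diff(occ[peak:length(occ)]) <= 0))
  # single-slice mask
  one <- cl
  keep <- which(apply(cl$mask, 3, any))[1]
  one$mask[, , -keep] <- FALSE
  p1 <- per_slice_profile(one)
  expect_equal(sum(p1$n_voxels > 0), 1)
})

test_that("measured volume is stable under halving the voxel spacing", {
  v05 <- {
    ph <- phantom_default()
    p <- segmentation_params(300, closing_radius_mm = 2.0)
    cav <- segment_cavity(ph$preop, threshold_bone(ph$preop, p), p,
                          side = ph$truth$unaffected_side,
                          landmarks = ph$landmarks, stop_plane = "landmarks")
    s <- side_landmarks(ph$landmarks, ph$truth$unaffected_side)
    compute_volume(clip_anterior(cav, anterior_clip_plane(s$L, s$M)))
  }
  v10 <- {
    ph <- phantom_coarse()
    p <- segmentation_params(300, closing_radius_mm = 2.0)
    cav <- segment_cavity(ph$preop, threshold_bone(ph$preop, p), p,
                          side = ph$truth$unaffected_side,
                          landmarks = ph$landmarks, stop_plane = "landmarks")
    s <- side_landmarks(ph$landmarks, ph$truth$unaffected_side)
    compute_volume(clip_anterior(cav, anterior_clip_plane(s$L, s$M)))
  }
  expect_lt(abs(v05 / v10 - 1), 0.01)
})
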