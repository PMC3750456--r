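labeled_template <- function() {
  cached("labeled_template", function() {
    ph <- phantom_noiseless()
    tm <- template_noiseless()
    aff <- ph$truth$affected_side
    s <- side_landmarks(ph$landmarks, aff)
    lm <- landmark_set(right = if (aff == "right") s else NULL,
                       left = if (aff == "left") s else NULL,
                       midline = ph$landmarks$midline)
    walls <- label_walls(tm, lm, ph$truth$mirror_plane, side = aff)
    list(phantom = ph, template = tm, walls = walls,
         nine = split_thirds(walls, tm))
  })
}

test_that("every vertex gets exactly one label and the 9 regions partition the walls", {
  lt <- labeled_template()
  lab <- lt$nine$label
  expect_length(lab, nrow(lt$template$vertices))
  expect_true(all(lab %in% c(wall_region_names(), "roof", "rim", "unassigned")))
  counts <- table(lab)
  expect_true(all(wall_region_names() %in% names(counts)))
  expect_true(all(counts[wall_region_names()] > 0))
  expect_identical(sum(counts), length(lab))
})

test_that("region areas conserve the total wall area", {
  lt <- labeled_template()
  va <- vertex_areas(lt$template)
  wall_total <- sum(va[lt$nine$label %in% wall_region_names()])
  per_region <- vapply(wall_region_names(),
                       function(r) sum(va[lt$nine$label == r]), numeric(1))
  expect_lt(abs(sum(per_region) / wall_total - 1), 1e-6)
})

test_that("data-driven labels agree with the generator's ground truth", {
  lt <- labeled_template()
  truth <- phantom_truth_labels(lt$phantom, lt$template)
  wall_of <- function(x) sub("_.*$", "", x)
  third_of <- function(x) sub("^.*_", "", x)
  on_wall <- truth$label %in% wall_region_names() &
    lt$nine$label %in% wall_region_names()
  expect_gt(mean(on_wall), 0.5)
  agree_wall <- mean(wall_of(lt$nine$label[on_wall]) ==
                     wall_of(truth$label[on_wall]))
  agree_third <- mean(third_of(lt$nine$label[on_wall]) ==
                      third_of(truth$label[on_wall]))
  expect_gte(agree_wall, 0.90)
  expect_gte(agree_third, 0.95)
})

test_that("the lowest patch of an axis-aligned half-ellipsoid is the floor", {
  lt <- labeled_template()
  v <- lt$template$vertices
  bottom <- v[, 3] < quantile(v[, 3], 0.02)
  # the bottom patch may graze the rim band; among wall labels it must be
  # floor only
  on_wall <- lt$nine$label %in% wall_region_names()
  expect_gt(sum(bottom & on_wall), 50)
  expect_true(all(grepl("^floor", lt$nine$label[bottom & on_wall])))
})

test_that("depth thirds use right-closed boundaries", {
  # synthetic wall strip along the depth axis: rim at y = 0, apex at y = -30
  n <- 7
  v <- cbind(0, -c(0, 5, 10, 10.0001, 15, 20, 29) - 1e-9, -10)
  v[4, 2] <- -10  # exactly at d = 1/3
  mesh <- surface_mesh(rbind(v, c(0, -30, -10)),
                       cbind(1:(n - 1), 2:n, n + 1))
  lab <- region_labeling(rep("floor", n + 1))
  out <- split_thirds(lab, mesh, rim_plane = plane3(c(0, 1, 0), c(0, 0, 0)),
                      apex = c(0, -30, 0))
  expect_equal(out$label[4], "floor_central")  # boundary vertex -> central
  expect_equal(out$label[1], "floor_anterior")
  expect_equal(out$label[8], "floor_posterior")
  # a uniform depth distribution splits close to equal thirds
  set.seed(61)
  depths <- runif(3000, 0, 30)
  vu <- cbind(0, -depths, -10)
  mu <- surface_mesh(rbind(vu, c(0, -30, -10)), cbind(1:2999, 2:3000, 3001))
  lu <- split_thirds(region_labeling(rep("floor", 3001)), mu,
                     rim_plane = plane3(c(0, 1, 0), c(0, 0, 0)),
                     apex = c(0, -30, 0))
  frac <- table(lu$label[1:3000]) / 3000
  expect_true(all(abs(frac - 1 / 3) < 0.05))
})

test_that("implant segmentation recovers the phantom sheet exactly", {
  ph <- phantom_noiseless()
  imp <- segment_implant(ph$postop, implant_threshold = 2000)
  expect_identical(unname(imp$mask), unname(ph$truth$implant_mask))
  expect_equal(imp$n_components, 1L)
  # pre-operative scan: empty mask plus a warning, not an error
  expect_warning(pre_imp <- segment_implant(ph$preop, 2000), "no implant")
  expect_equal(pre_imp$n_voxels, 0L)
  # threshold below bone leaks into the skeleton: flagged by the report
  leaky <- segment_implant(ph$postop, implant_threshold = 500)
  expect_gt(leaky$n_voxels, 10 * imp$n_voxels)
})

test_that("implant coverage concentrates on the reconstructed floor", {
  ph <- phantom_noiseless()
  tm <- template_noiseless()
  truth <- phantom_truth_labels(ph, tm)
  imp <- segment_implant(ph$postop, 2000)
  cov <- implant_coverage(truth, tm, imp, projection_distance_mm = 2)
  expect_true(all(cov$coverage >= 0 & cov$coverage <= 1))
  expect_gt(cov$coverage[cov$region == "floor_anterior"], 0.9)
  expect_lt(cov$coverage[cov$region == "medial_posterior"], 0.1)
  expect_lt(cov$coverage[cov$region == "lateral_posterior"], 0.1)
  # empty implant: all-zero coverage
  empty <- suppressWarnings(segment_implant(ph$preop, 2000))
  cov0 <- implant_coverage(truth, tm, empty, 2)
  expect_true(all(cov0$coverage == 0))
  # coverage is monotone in the projection distance
  cov4 <- implant_coverage(truth, tm, imp, projection_distance_mm = 4)
  expect_true(all(cov4$coverage >= cov$coverage - 1e-12))
})

test_that("the medial-floor transition band sits between the two walls", {
  lt <- labeled_template()
  band <- transition_zone(lt$nine, lt$template, band_mm = 2)
  expect_gt(sum(band), 0)
  expect_true(all(grepl("^(medial|floor)", lt$nine$label[band])))
})
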