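test_that("identical meshes give an all-zero deviation map", {
  m <- icosphere(12, 3)
  map <- signed_distance(m, m, 5)
  expect_false(any(map$missing))
  expect_lt(max(abs(map$deviation_mm)), 1e-9)
})

test_that("concentric spheres recover the analytic 1 mm gap", {
  inner <- icosphere(15, 5)   # ~0.5 mm edge length at r = 15
  outer <- icosphere(16, 5)
  map <- signed_distance(inner, outer, 5)
  expect_false(any(map$missing))
  expect_lt(abs(mean(abs(map$deviation_mm)) - 1.0), 0.05)
  # uniform sign: outer surface lies outside the inner template everywhere
  expect_true(all(map$deviation_mm > 0))
  map_rev <- signed_distance(outer, inner, 5)
  expect_true(all(map_rev$deviation_mm < 0))
  # Hausdorff-type sanity: both directions agree on the mean gap
  expect_lt(abs(mean(abs(map$deviation_mm)) /
                mean(abs(map_rev$deviation_mm)) - 1), 0.1)
})

test_that("accelerated closest-point queries match the exhaustive scan", {
  set.seed(51)
  for (mesh in list(icosphere(10, 2),
                    surface_mesh(matrix(rnorm(45, sd = 8), 15, 3),
                                 matrix(sample(15, 30, replace = TRUE), 10, 3)))) {
    mesh <- clean_mesh(mesh)
    q <- matrix(rnorm(60, sd = 12), 20, 3)
    fast <- orbitqc:::.closest_point_mesh(mesh$vertices, mesh$faces, q, Inf)
    ref <- brute_force_distance(mesh, q)
    expect_lt(max(abs(fast$dist - ref)), 1e-9)
  }
})

test_that("vertices beyond the correspondence cap are missing, not zero", {
  m <- icosphere(5, 2)
  far <- surface_mesh(m$vertices + 100, m$faces)
  map <- signed_distance(far, m, max_correspondence_mm = 10)
  expect_true(all(map$missing))
  expect_true(all(is.na(map$deviation_mm)))
})

test_that("the deviation map is equivariant under joint translation", {
  tm <- icosphere(10, 3)
  tg <- icosphere(11, 3)
  map1 <- signed_distance(tm, tg, 5)
  shift <- c(12.25, -3.5, 7.75)
  map2 <- signed_distance(surface_mesh(tm$vertices + rep(shift, each = nrow(tm$vertices)), tm$faces),
                          surface_mesh(tg$vertices + rep(shift, each = nrow(tg$vertices)), tg$faces),
                          5)
  expect_lt(max(abs(map1$deviation_mm - map2$deviation_mm)), 1e-9)
})

test_that("colorization follows the symmetric diverging scheme", {
  map <- structure(list(deviation_mm = c(0, 1.5, -1.5, 3, -3, 0.75, NA),
                        missing = c(rep(FALSE, 6), TRUE),
                        distance_mm = abs(c(0, 1.5, -1.5, 3, -3, 0.75, NA))),
                   class = "deviation_map")
  rgb <- colorize(map, clamp_mm = 1.5)
  expect_equal(rgb[1, ], c(red = 0, green = 1, blue = 0))    # green at zero
  expect_equal(rgb[2, ], c(red = 1, green = 0, blue = 0))    # red at +clamp
  expect_equal(rgb[3, ], c(red = 0, green = 0, blue = 1))    # blue at -clamp
  expect_equal(rgb[4, ], rgb[2, ])                           # saturation
  expect_equal(rgb[5, ], rgb[3, ])
  expect_equal(rgb[6, ], c(red = 0.5, green = 0.5, blue = 0))
  expect_equal(unname(rgb[7, ]), rep(0.5, 3))                # missing = grey
})

test_that("per-region summaries aggregate constructed maps correctly", {
  lbl <- region_labeling(rep(c("floor_anterior", "medial_central"), each = 50))
  dev <- c(rep(1, 50), rep(0, 50))
  map <- structure(list(deviation_mm = dev, missing = rep(FALSE, 100),
                        distance_mm = abs(dev)), class = "deviation_map")
  ds <- deviation_summary(map, lbl)
  expect_equal(ds$mean_mm[ds$region == "floor_anterior"], 1)
  expect_equal(ds$sd_mm[ds$region == "floor_anterior"], 0)
  expect_equal(ds$mean_mm[ds$region == "medial_central"], 0)
  # all-zero map: every populated region reports 0 +- 0
  map0 <- structure(list(deviation_mm = rep(0, 100), missing = rep(FALSE, 100),
                         distance_mm = rep(0, 100)), class = "deviation_map")
  ds0 <- deviation_summary(map0, lbl)
  pop <- ds0$n_valid > 0
  expect_true(all(ds0$mean_mm[pop] == 0) && all(ds0$sd_mm[pop] == 0))
  # an unpopulated region reports as empty, not an error
  expect_true(any(ds0$n_vertices == 0))
  expect_true(all(is.na(ds0$mean_mm[!pop])))
  # missing vertices are excluded from moments and counted in the fraction
  mapm <- structure(list(deviation_mm = c(rep(1, 25), rep(NA, 25), rep(0, 50)),
                         missing = c(rep(FALSE, 25), rep(TRUE, 25),
                                     rep(FALSE, 50)),
                         distance_mm = rep(0, 100)), class = "deviation_map")
  dsm <- deviation_summary(mapm, lbl)
  expect_equal(dsm$missing_fraction[dsm$region == "floor_anterior"], 0.5)
  expect_equal(dsm$mean_mm[dsm$region == "floor_anterior"], 1)
})
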