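test_that("the default phantom hits the analytic clipped cavity volume", {
  ph <- phantom_default()
  # (2/3) pi a b c of the generator's semi-axes equals the calibration target
  a <- ph$spec$semi_axes
  expect_equal(2 / 3 * pi * prod(a) / 1000, 26.6, tolerance = 1e-9)
  expect_lt(abs(ph$truth$volumes_ml[["unaffected"]] / 26.6 - 1), 0.02)
})

test_that("the injected enlargement matches the requested added volume", {
  ph <- phantom_default()
  gain <- ph$truth$volumes_ml[["affected"]] - ph$truth$volumes_ml[["unaffected"]]
  expect_lt(abs(gain - 3.4), 0.1)
})

test_that("an unattainable added volume errors with the attainable maximum", {
  spec <- phantom_spec(fracture = list(wall = "floor", region = "central",
                                       added_volume_ml = 50,
                                       max_bulge_mm = 2))
  expect_error(generate_phantom(spec), "attainable maximum")
})

test_that("phantom generation is bit-reproducible from the seed", {
  a <- generate_phantom(phantom_spec(spacing_mm = 1, seed = 42L))
  b <- generate_phantom(phantom_spec(spacing_mm = 1, seed = 42L))
  expect_identical(a$truth$volumes_ml, b$truth$volumes_ml)
  expect_identical(a$preop$data, b$preop$data)
  expect_identical(a$postop$data, b$postop$data)
  c_ <- generate_phantom(phantom_spec(spacing_mm = 1, seed = 43L))
  expect_false(identical(a$preop$data, c_$preop$data))
})

test_that("asymmetry scales the contralateral cavity volume cubically", {
  ph <- generate_phantom(phantom_spec(spacing_mm = 1, asymmetry = 1.05,
                                      fracture = NULL, reconstruction = NULL,
                                      noise_sigma = c(CT = 0, CBCT = 0)))
  # affected side keeps the calibrated volume; left (unaffected here) is
  # scaled by 1.05^3
  expect_lt(abs(ph$truth$volumes_ml[["unaffected"]] /
                (26.6 * 1.05^3) - 1), 0.02)
  expect_lt(abs(ph$truth$volumes_ml[["affected"]] / 26.6 - 1), 0.02)
})

test_that("a perfectly symmetric intact phantom mirrors onto itself", {
  ph <- phantom_intact()
  m <- extract_surface(ph$truth$cavity_masks$unaffected, ph$truth$spacing,
                       ph$truth$origin)
  tm <- reflect_mesh(m, ph$truth$mirror_plane)
  other <- extract_surface(ph$truth$cavity_masks$affected, ph$truth$spacing,
                           ph$truth$origin)
  map <- signed_distance(tm, other, 5)
  expect_lt(mean(abs(map$deviation_mm), na.rm = TRUE), 0.2)
})

test_that("synthetic cohorts follow the study composition", {
  rec <- generate_cohort(n = 94, seed = 11)
  expect_equal(nrow(rec), 94)
  counts <- table(factor(rec$fracture_class, levels = fracture_classes()))
  probs <- c(34, 20, 36, 4) / 94
  expect_gt(suppressWarnings(stats::chisq.test(counts, p = probs))$p.value,
            1e-4)
  expect_gt(sum(rec$group == "Navi"), sum(rec$group == "conv"))
  expect_gt(sum(rec$gender == "male"), sum(rec$gender == "female"))
  # reproducibility
  expect_identical(generate_cohort(20, seed = 2), generate_cohort(20, seed = 2))
  expect_false(identical(generate_cohort(20, seed = 2),
                         generate_cohort(20, seed = 3)))
})
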