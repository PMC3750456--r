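test_that("midsagittal estimation is exact for coplanar points", {
  pl <- estimate_midsagittal(rbind(c(0, 1, 0), c(0, 0, 1), c(0, -3, 2)))
  expect_equal(abs(pl$normal), c(1, 0, 0))
  expect_lt(abs(plane_signed_distance(pl, c(0, 10, -4))), 1e-9)
  expect_error(estimate_midsagittal(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))),
               "collinear")
  expect_error(estimate_midsagittal(rbind(c(0, 0, 0), c(0, 0, 1))), "3 midline")
})

test_that("midsagittal estimation tolerates landmark picking noise", {
  ph <- phantom_coarse()
  truth_n <- ph$truth$mirror_plane$normal
  pts <- ph$landmarks$midline
  set.seed(41)
  errs <- replicate(100, {
    noisy <- pts + matrix(rnorm(length(pts), 0, 0.2), nrow(pts))
    est <- estimate_midsagittal(noisy)
    acos(min(1, abs(sum(est$normal * truth_n)))) * 180 / pi
  })
  expect_lt(mean(errs), 1)
  # exact landmarks reproduce the generator's plane
  est <- estimate_midsagittal(ph$landmarks)
  expect_lt(acos(min(1, abs(sum(est$normal * truth_n)))) * 180 / pi, 1e-6)
  expect_lt(abs(plane_signed_distance(est, ph$truth$mirror_plane$point)), 1e-6)
})

test_that("self-registration returns the identity", {
  tm <- template_noiseless()
  fit <- icp_register(tm, rep(TRUE, nrow(tm$vertices)), tm,
                      registration_params(max_points = 2000))
  expect_true(fit$converged)
  expect_lt(fit$residuals$max, 1e-9)
  expect_lt(rotation_angle_deg(fit$transform), 1e-7)
  expect_lt(sqrt(sum(fit$transform$t^2)), 1e-7)
})

test_that("ICP recovers a known rigid perturbation on noiseless surfaces", {
  tm <- template_noiseless()
  ctr <- colMeans(tm$vertices)
  tr_true <- compose_transform(rigid_transform(diag(3), c(2, 1, 0.5)),
                               rotation_about(c(0, 0, 1), 5, center = ctr))
  moved <- transform_mesh(tm, invert_transform(tr_true))
  fit <- icp_register(moved, rep(TRUE, nrow(tm$vertices)), tm,
                      registration_params())
  err <- compose_transform(invert_transform(tr_true), fit$transform)
  expect_lt(rotation_angle_deg(err), 0.05)
  expect_lt(sqrt(sum(err$t^2)), 0.01)
  expect_lt(fit$residuals$rms, 0.05)
})

test_that("the fitted transform is rigid and deterministic", {
  tm <- template_noiseless()
  tg <- target_noiseless()
  lbl <- phantom_truth_labels(phantom_noiseless(), tm)
  roi <- !(grepl("^floor", lbl$label) | lbl$label %in% c("rim", "unassigned"))
  fit1 <- icp_register(tm, roi, tg, registration_params())
  fit2 <- icp_register(tm, roi, tg, registration_params())
  expect_identical(fit1$transform$R, fit2$transform$R)
  expect_identical(fit1$transform$t, fit2$transform$t)
  p <- tm$vertices[seq(1, nrow(tm$vertices), length.out = 50), ]
  q <- apply_transform(fit1$transform, p)
  expect_lt(max(abs(dist(q) - dist(p))), 1e-9)
})

test_that("excluding the reconstructed wall from the ROI preserves the
           injected floor deformation", {
  ph <- phantom_noiseless()
  tm <- template_noiseless()
  tg <- target_noiseless()
  amp <- ph$truth$residual$amplitude_mm
  lbl <- phantom_truth_labels(ph, tm)
  floor_excl <- !(grepl("^floor", lbl$label) | lbl$label %in% c("rim", "unassigned"))
  fit <- icp_register(tm, floor_excl, tg, registration_params())
  map <- signed_distance(transform_mesh(tm, fit$transform), tg, 10)
  ds <- deviation_summary(map, lbl)
  peak_excl <- ds$peak_abs_mm[ds$region == "floor_anterior"]
  # roof/unaffected walls stay tight while the deformation is not absorbed
  expect_lt(ds$sd_mm[ds$region == "medial_central"], 0.1)
  expect_lt(abs(peak_excl - amp), 0.1 * amp)
  # registering WITH the deformed floor included (and no trimming) drags
  # the template toward the bulge and biases the measured deviation --
  # the reason the ROI is restricted to unaffected areas
  fit_in <- icp_register(tm, rep(TRUE, nrow(tm$vertices)), tg,
                         registration_params(trim_fraction = 0))
  map_in <- signed_distance(transform_mesh(tm, fit_in$transform), tg, 10)
  ds_in <- deviation_summary(map_in, lbl)
  bias_in <- abs(ds_in$peak_abs_mm[ds_in$region == "floor_anterior"] - amp)
  expect_gt(bias_in, abs(peak_excl - amp))
})

test_that("an emptied ROI is rejected", {
  tm <- template_noiseless()
  expect_error(roi_selector(tm, include = rep(FALSE, nrow(tm$vertices))),
               "at least")
  expect_error(icp_register(tm, rep(FALSE, nrow(tm$vertices)),
                            target_noiseless()), "ROI is empty")
})
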