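test_that("trabecular generator hits the target volume fraction and is seeded", {
  sp <- trabecular_spec(extents = c(32, 32, 32), target_bvtv = 0.5, seed = 7)
  a <- make_trabecular(sp, thickness_reference = FALSE)
  b <- make_trabecular(sp, thickness_reference = FALSE)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$ground_truth$mask, b$ground_truth$mask)
  expect_lt(abs(a$ground_truth$bvtv - 0.5), 0.005)
  expect_equal(a$ground_truth$bvtv, mean(a$ground_truth$mask))
  expect_true(all(a$volume$data >= 0 & a$volume$data <= 1))
})

test_that("doubling the feature scale roughly doubles the strut thickness", {
  base <- trabecular_spec(extents = c(96, 96, 96), feature_scale_um = 150,
                          target_bvtv = 0.3, noise_sd = 0, blur_sd_vox = 0,
                          seed = 21)
  dbl <- trabecular_spec(extents = c(96, 96, 96), feature_scale_um = 300,
                         target_bvtv = 0.3, noise_sd = 0, blur_sd_vox = 0,
                         seed = 21)
  m1 <- make_trabecular(base, thickness_reference = FALSE)$ground_truth$mask
  m2 <- make_trabecular(dbl, thickness_reference = FALSE)$ground_truth$mask
  th1 <- local_thickness(m1, "foreground", 50)
  th2 <- local_thickness(m2, "foreground", 50)
  ratio <- mean(th2[m2]) / mean(th1[m1])
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("trabecular spec rejects invalid parameters", {
  expect_error(trabecular_spec(target_bvtv = 1.2), "inside")
  expect_error(trabecular_spec(bone_level = 0.1, background_level = 0.5),
               "exceed")
  expect_error(make_trabecular(trabecular_spec(extents = c(4, 4, 4),
                                               feature_scale_um = 600)),
               "too small")
})

test_that("plate phantom has exact analytic volume fraction and geometry", {
  pp <- make_plate_phantom(6, 10, c(48, 16, 16), voxel_size_um = 100)
  expect_equal(pp$ground_truth$bvtv, 6 / 16)
  expect_equal(pp$ground_truth$tbth_um, 600)
  expect_equal(pp$ground_truth$tbsp_um, 1000)
  th <- local_thickness(pp$ground_truth$mask, "foreground", 100)
  expect_true(all(abs(th[pp$ground_truth$mask] - 600) < 1e-9))
  sp <- local_thickness(pp$ground_truth$mask, "background", 100)
  expect_true(all(abs(sp[!pp$ground_truth$mask] - 1000) < 1e-9))
})

test_that("line-pair phantom renders the designed bar periods", {
  spec <- line_pair_spec(noise_sd = 0, slices = 1)
  ph <- make_line_pair_phantom(spec)
  # the fifth-group analogue near 8 lp/cm: check the rendered period by
  # autocorrelation of the band profile
  for (g in c(3L, 5L, 6L)) {
    roi <- ph$rois$groups[[g]]
    prof <- ph$volume$data[1, roi$rows[1] + 1, ]
    prof <- prof - mean(prof)
    ac <- stats::acf(prof, lag.max = 40, plot = FALSE)$acf[, 1, 1]
    period_design <- 10000 / (roi$freq_lp_cm * spec$pixel_size_um)
    # first positive-lag peak of the autocorrelation
    peak <- which.max(ac[-1])
    expect_lt(abs(peak - period_design), 1)
  }
  # 8.3 lp/cm at 200 um pixels has a ~6.02 px period
  expect_equal(10000 / (8.3 * 200), 6.024, tolerance = 1e-3)
  expect_error(line_pair_spec(group_frequencies_lp_per_cm = c(2, 2, 3, 4, 5, 6)),
               "strictly increasing")
  expect_error(line_pair_spec(group_frequencies_lp_per_cm = c(2, 3, 4, 5, 6, 30)),
               "not representable")
})

test_that("line-pair uniform regions have exact levels and zero noise sd", {
  ph <- make_line_pair_phantom(line_pair_spec(noise_sd = 0, slices = 2))
  sl <- ph$volume$data[1, , ]
  m1 <- ph$rois$materials[[1]]
  expect_equal(mean(sl[m1$rows[1]:m1$rows[2], m1$cols[1]:m1$cols[2]]),
               m1$level)
  nz <- ph$rois$noise
  expect_equal(sd(sl[nz$rows[1]:nz$rows[2], nz$cols[1]:nz$cols[2]]), 0)
  # seeded noise makes slices differ but deterministically
  ph2 <- make_line_pair_phantom(line_pair_spec(noise_sd = 0.05, slices = 2,
                                               seed = 9))
  ph3 <- make_line_pair_phantom(line_pair_spec(noise_sd = 0.05, slices = 2,
                                               seed = 9))
  expect_identical(ph2$volume$data, ph3$volume$data)
  expect_gt(sd(ph2$volume$data[1, , ] - ph2$volume$data[2, , ]), 0)
})

test_that("edge phantom renders a clean step and recovers blur sigma", {
  e0 <- make_edge_phantom(0, c(0, 1), c(1, 32, 32), edge_col = 16)
  expect_true(all(e0$data %in% c(0, 1)))
  expect_true(all(e0$data[1, , 1:16] == 0) && all(e0$data[1, , 17:32] == 1))
  # blur the edge and fit an error function to the mean profile
  sl <- gaussian_blur(e0$data[1, , ], c(0, 1))
  prof <- colMeans(sl)
  fit <- stats::nls(prof ~ pnorm(seq_along(prof), m, s),
                    start = list(m = 16, s = 2))
  expect_equal(unname(coef(fit)["s"]), 1.0, tolerance = 0.05)
})
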