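test_that("the Gaussian weight map has the closed-form profile", {
  w <- gaussian_weight_map(64, 16, 2)
  # corner sits 31.5 pixels off-centre per axis
  expect_equal(w[1, 1], exp(-(2 * 31.5^2) / (2 * 16^2)), tolerance = 1e-6)
  # symmetric under both flips
  expect_equal(w, w[64:1, ], tolerance = 1e-12)
  expect_equal(w, w[, 64:1], tolerance = 1e-12)
  # odd windows peak at exactly 1 in the centre
  wo <- gaussian_weight_map(33, 8, 2)
  expect_equal(wo[17, 17], 1)
  expect_true(all(w >= 1e-4))
  expect_error(gaussian_weight_map(16, 0), "positive")
})

test_that("a constant stub passes through the blend unchanged", {
  vol <- new_volume(array(runif(4 * 24 * 40), c(4, 24, 40)), 200, "float01")
  for (step in c(8L, 16L)) {
    out <- sliding_window_sr(vol, constant_stub(0.5),
                             sliding_window_config(step_lr = step))
    expect_equal(dim(out$data), c(4L, 96L, 160L))
    expect_true(all(out$data == 0.5))
  }
})

test_that("a perfect oracle reconstructs the true volume through the blend", {
  hr <- with_seed(21, new_volume(array(runif(4 * 128 * 128), c(4, 128, 128)),
                                 50, "float01"))
  lr <- new_volume(block_average(hr$data, 4L, 2:3), 200, "float01")
  out <- sliding_window_sr(lr, oracle_stub(hr),
                           sliding_window_config(plane = "axial"))
  expect_lt(max(abs(out$data - hr$data)), 1e-6)
  # 3D path
  hr3 <- with_seed(22, new_volume(array(runif(64^3), c(64, 64, 64)), 50,
                                  "float01"))
  lr3 <- new_volume(block_average(hr3$data, 4L), 200, "float01")
  out3 <- bonesr:::sr_volume_3d(lr3, oracle_stub(hr3),
                                sliding_window_config())
  expect_lt(max(abs(out3$data - hr3$data)), 1e-6)
})

test_that("blending is a convex combination of tile predictions", {
  vol <- new_volume(array(runif(2 * 24 * 24), c(2, 24, 24)), 200, "float01")
  stub <- function_stub(function(tile) {
    # nearest-neighbour x4 with a constant offset, bounded in [0.2, 0.9]
    t4 <- tile[rep(seq_len(nrow(tile)), each = 4),
               rep(seq_len(ncol(tile)), each = 4)]
    pmin(pmax(t4, 0.2), 0.9)
  })
  out <- sliding_window_sr(vol, stub, sliding_window_config())
  expect_gte(min(out$data), 0.2 - 1e-12)
  expect_lte(max(out$data), 0.9 + 1e-12)
})

test_that("orthogonal averaging is exact on constants and consistent per plane", {
  vol <- new_volume(array(0.5, c(8, 16, 16)), 200, "float01")
  out <- orthogonal_average(vol, constant_stub(0.5))
  expect_equal(dim(out$data), c(32L, 64L, 64L))
  expect_equal(max(abs(out$data - 0.5)), 0, tolerance = 1e-9)
  expect_equal(out$voxel_size_um, rep(50, 3))
})

test_that("tricubic interpolation reproduces linear ramps and extents", {
  n <- 8
  ramp <- array(seq(0.1, 0.9, length.out = n), c(n, n, n))  # varies on axis 1
  vol <- new_volume(ramp, 200, "float01")
  up <- tricubic_upscale(vol)
  expect_equal(dim(up$data), c(32L, 32L, 32L))
  # interior of the upscaled ramp is linear in the slice coordinate
  interior <- up$data[9:24, 16, 16]
  expect_lt(max(abs(diff(interior) - diff(interior)[1])), 1e-6)
  # constants are preserved exactly
  cv <- new_volume(array(0.3, c(4, 4, 4)), 200, "float01")
  expect_equal(max(abs(tricubic_upscale(cv)$data - 0.3)), 0, tolerance = 1e-12)
})

test_that("the conventional pipeline smooths noise and keeps constants flat", {
  cv <- new_volume(array(0.4, c(8, 8, 8)), 200, "float01")
  out <- conventional_enhance(cv)
  expect_true(all(out$data == 0))  # degenerate range maps to zero by contract
  # noisy step edge: within-region variance shrinks
  with_seed(9, {
    step <- array(0.2, c(8, 24, 24)); step[, , 13:24] <- 0.8
    noisy <- clip01(step + array(rnorm(length(step), sd = 0.05), dim(step)))
    enh <- conventional_enhance(new_volume(noisy, 200, "float01"))
    v_pre <- var(as.vector(noisy[, , 1:10]))
    v_post <- var(as.vector(enh$data[, , 1:10]))
    expect_lt(v_post, v_pre)
  })
  # the median stage removes isolated salt-and-pepper impulses
  imp <- array(0, c(8, 8, 8)); imp[4, 4, 4] <- 1
  expect_equal(max(median_filter(imp, 3L)), 0)
})
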