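test_that("cascade presets enforce the x4 relation", {
  cs <- resolution_cascade("200to50")
  expect_equal(cs$input_um, 200)
  expect_equal(cs$target_um, 50)
  expect_equal(cs$factor, 4L)
  expect_error(resolution_cascade(100, 30), "4")
})

test_that("make_target resamples to the expected grid and smooths", {
  cs <- resolution_cascade("200to50")
  hr <- with_seed(5, new_volume(array(runif(104 * 24 * 24), c(24, 104, 24)),
                                c(26.7, 26.7, 26.7), "float01"))
  tg <- make_target(hr, cs)
  expect_equal(dim(tg$data)[2], round(104 * 26.7 / 50))  # 56
  expect_equal(tg$voxel_size_um, rep(50, 3))
  # constants survive, white noise loses variance
  const <- new_volume(array(0.4, c(16, 16, 16)), 25, "float01")
  expect_equal(max(abs(make_target(const, cs)$data - 0.4)), 0, tolerance = 1e-9)
  expect_lt(var(as.vector(tg$data)), var(as.vector(hr$data)))
  expect_error(make_target(new_volume(array(0.1, c(4, 4, 4)), 80), cs),
               "downsamples")
})

test_that("make_input follows the 128 -> 32 shape law and degrades impulses", {
  tgt <- with_seed(2, new_volume(array(runif(128^2 * 8), c(8, 128, 128)),
                                 50, "float01"))
  lr <- make_input(tgt, dims = 2L)
  expect_equal(dim(lr$data), c(8L, 32L, 32L))
  expect_equal(lr$voxel_size_um, c(50, 200, 200))
  lr3 <- make_input(new_volume(tgt$data[1:8, 1:64, 1:64], 50), dims = 3L)
  expect_equal(dim(lr3$data), c(2L, 16L, 16L))
  # constants pass through
  cv <- new_volume(array(0.3, c(8, 16, 16)), 50, "float01")
  expect_equal(max(abs(make_input(cv, 2L)$data - 0.3)), 0, tolerance = 1e-12)
  # a single bright voxel is attenuated and spread
  imp <- array(0, c(12, 12, 12)); imp[6, 6, 6] <- 1
  out <- make_input(new_volume(imp, 50), dims = 3L)$data
  expect_lt(max(out), 1)
  expect_gt(sum(out > 1e-6), 1)
  expect_error(make_input(new_volume(array(0.1, c(2, 2, 2)), 50), 3L), ">= 4")
})

test_that("degradation commutes with in-plane flips (symmetric kernels)", {
  tgt <- with_seed(9, new_volume(array(runif(32 * 32 * 4), c(4, 32, 32)),
                                 50, "float01"))
  flip <- function(a) a[, , rev(seq_len(dim(a)[3]))]
  a <- make_input(new_volume(flip(tgt$data), 50), dims = 2L)$data
  b <- flip(make_input(tgt, dims = 2L)$data)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("patch tiling counts follow the lattice formula", {
  lr2 <- new_volume(array(0.5, c(48, 48, 48)), 200, "float01")
  hr2 <- new_volume(array(0.5, c(192, 192, 192)), 50, "float01")
  # floor((48 - 32)/16) + 1 = 2 start positions per axis
  expect_length(tile_patches(lr2, hr2, patch_lr = 32L, stride = 16L), 8)
  lr2b <- new_volume(array(0.5, c(48, 48, 48)), 200, "float01")
  hr2b <- new_volume(array(0.5, c(192, 192, 192)), 50, "float01")
  expect_length(tile_patches(lr2b, hr2b, patch_lr = 16L, stride = 16L), 27)
  lr3 <- new_volume(array(0.5, c(32, 32, 32)), 200, "float01")
  hr3 <- new_volume(array(0.5, c(128, 128, 128)), 50, "float01")
  expect_length(tile_patches(lr3, hr3, patch_lr = 32L), 1)
  p <- tile_patches(lr3, hr3, patch_lr = 32L)[[1]]
  expect_equal(dim(p$hr), 4L * dim(p$lr))
  expect_error(tile_patches(lr3, lr3, patch_lr = 16L), "misaligned")
})

test_that("2D tiling pairs input slices with centre target slices", {
  lr <- new_volume(array(seq(0, 1, length.out = 2 * 16 * 16), c(2, 16, 16)),
                   200, "float01")
  hr <- new_volume(array(runif(8 * 64 * 64), c(8, 64, 64)), 50, "float01")
  ps <- tile_patches(lr, hr, patch_lr = 16L, dims = 2L)
  expect_length(ps, 2)
  expect_equal(ps[[1]]$hr, hr$data[2, , ])
  expect_equal(ps[[2]]$hr, hr$data[6, , ])
})

test_that("grouped k-fold never leaks patients and balances fold sizes", {
  mk <- function(pid) patch_pair(matrix(0, 4, 4), matrix(0, 16, 16),
                                 patient_id = pid)
  pairs <- lapply(rep(paste0("p", 1:11), each = 3), mk)
  splits <- grouped_kfold(pairs, k = 4L, seed = 1)
  pid <- vapply(pairs, `[[`, character(1), "patient_id")
  sizes <- integer(4)
  for (f in seq_along(splits)) {
    expect_length(intersect(pid[splits[[f]]$train], pid[splits[[f]]$val]), 0)
    sizes[f] <- length(unique(pid[splits[[f]]$val]))
  }
  expect_setequal(sizes, c(3, 3, 3, 2))
  # folds partition all indices
  all_val <- sort(unlist(lapply(splits, `[[`, "val")))
  expect_identical(all_val, seq_along(pairs))
  # 8 patients over 4 folds -> 2 per fold
  pairs8 <- lapply(rep(paste0("q", 1:8), each = 2), mk)
  s8 <- grouped_kfold(pairs8, 4L, seed = 2)
  expect_true(all(vapply(s8, function(s)
    length(unique(vapply(pairs8[s$val], `[[`, character(1), "patient_id"))),
    integer(1)) == 2L))
  expect_error(grouped_kfold(pairs8[1:4], k = 4L), "fewer distinct patients")
})
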