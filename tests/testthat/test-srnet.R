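nf <- bonesr:::net_forward
nb <- bonesr:::net_backward

test_that("the network maps n to 4n per spatial axis in 2D and 3D", {
  m2 <- build_network(sr_network_config(2, base_channels = 6, seed = 3))
  expect_equal(dim(predict_tile(m2, matrix(runif(256), 16, 16))), c(64L, 64L))
  expect_equal(dim(predict_tile(m2, matrix(runif(64), 8, 8))), c(32L, 32L))
  m3 <- build_network(sr_network_config(3, base_channels = 4, seed = 3))
  expect_equal(dim(predict_tile(m3, array(runif(8^3), c(8, 8, 8)))),
               c(32L, 32L, 32L))
  expect_error(predict_tile(m3, matrix(0.5, 8, 8)), "dims")
  expect_error(sr_network_config(4), "dims must be 2 or 3")
})

test_that("initialization is reproducible from the seed", {
  a <- build_network(sr_network_config(2, base_channels = 6, seed = 3))
  b <- build_network(sr_network_config(2, base_channels = 6, seed = 3))
  c <- build_network(sr_network_config(2, base_channels = 6, seed = 4))
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("constant inputs produce spatially constant outputs (no checkerboard)", {
  m <- build_network(sr_network_config(2, base_channels = 8, seed = 11))
  out <- nf(m, matrix(0.5, 16, 16))$out
  expect_lt(diff(range(out)), 1e-5)
})

test_that("pixel losses match hand-computed values", {
  p <- matrix(c(0.1, 0.4, 0.5, 0.8), 2, 2)
  t <- p + 0.1
  expect_equal(mse_loss(p, t), 0.01)
  expect_equal(mae_loss(p, t), 0.1)
  expect_equal(mse_loss(p, p), 0)
  set.seed(8)
  a <- matrix(runif(16), 4, 4); b <- matrix(runif(16), 4, 4)
  expect_equal(mse_loss(a, b), sum((a - b)^2) / 16)
  expect_equal(mae_loss(a, b), sum(abs(a - b)) / 16)
  expect_error(mse_loss(a, matrix(0, 2, 8)), "shape")
})

test_that("total variation is normalized so the unit ramp scores 1", {
  ramp <- matrix(c(0, 1, 2, 3), 1, 4)
  expect_equal(tv_loss(ramp), 1)
  expect_equal(tv_loss(matrix(0.7, 5, 5)), 0)
  # blurring a checkerboard reduces TV
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_gt(tv_loss(cb), tv_loss(gaussian_blur(cb, 1)))
})

test_that("SSIM has its analytic fixed points and symmetry", {
  set.seed(5)
  a <- matrix(runif(16 * 16), 16, 16)
  expect_equal(ssim(a, a), 1)
  expect_equal(structure_loss(a, a), 0)
  g <- matrix(seq(0, 1, length.out = 256), 16, 16)
  expect_lt(ssim(g, 1 - g), 0)
  b <- matrix(runif(16 * 16), 16, 16)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_error(ssim(matrix(0.1, 8, 8), matrix(0.2, 8, 8)), "window")
})

test_that("the perceptual extractor is frozen, seeded and discriminative", {
  fx <- feature_extractor(2, seed = 42)
  fx2 <- feature_extractor(2, seed = 42)
  set.seed(1)
  a <- matrix(runif(256), 16, 16); b <- matrix(runif(256), 16, 16)
  expect_identical(perceptual_loss(a, b, fx), perceptual_loss(a, b, fx2))
  expect_equal(perceptual_loss(a, a, fx), 0)
  expect_gt(perceptual_loss(a, b, fx), 0)
  expect_error(feature_extractor(2, backend = "pretrained_vgg16"),
               "seeded_random_conv")
})

test_that("composite recipes combine their terms with the published weights", {
  set.seed(2)
  p <- matrix(runif(256), 16, 16); t <- matrix(runif(256), 16, 16)
  fx <- feature_extractor(2)
  expect_equal(composite_loss("baseline", p, t),
               0.8 * mse_loss(p, t) + 0.2 * tv_loss(p))
  expect_equal(composite_loss("structure", p, t), 1 - ssim(p, t))
  expect_equal(composite_loss("visual", p, t, fx = fx),
               0.1 * mae_loss(p, t) + 1.0 * tv_loss(p) +
                 1.0 * perceptual_loss(p, t, fx))
  # identical pair leaves only the TV of the target in the baseline recipe
  expect_equal(composite_loss("baseline", t, t), 0.2 * tv_loss(t))
  expect_equal(composite_loss("structure", t, t), 0)
  expect_error(composite_loss("visual", p, t), "feature extractor")
})

test_that("every loss gradient matches finite differences", {
  set.seed(31)
  p <- matrix(runif(256), 16, 16); t <- matrix(runif(256), 16, 16)
  fx <- feature_extractor(2)
  for (rec in c("baseline", "structure", "visual")) {
    cl <- composite_loss(rec, p, t, fx = fx, grad = TRUE)
    for (r in 1:4) {
      i <- sample(256, 1); eps <- 1e-6
      p2 <- p; p2[i] <- p2[i] + eps
      num <- (composite_loss(rec, p2, t, fx = fx) - cl$value) / eps
      expect_equal(cl$grad[i], num, tolerance = 1e-4)
    }
  }
})

test_that("backpropagated parameter gradients match finite differences", {
  set.seed(13)
  m <- build_network(sr_network_config(2, n_residual_blocks = 2,
                                       base_channels = 3, seed = 7))
  x <- matrix(runif(64), 8, 8); t <- matrix(runif(1024), 32, 32)
  fwd <- nf(m, x, keep_cache = TRUE)
  cl <- mse_loss(fwd$out, t, grad = TRUE)
  g <- nb(m, fwd$caches, cl$grad)
  leaves <- bonesr:::param_leaves(m$params)
  for (k in sample(seq_along(leaves), 8)) {
    pth <- leaves[[k]]
    W <- bonesr:::get_path(m$params, pth)
    i <- sample(length(W), 1); eps <- 1e-6
    m2 <- m; W2 <- W; W2[i] <- W2[i] + eps
    m2$params <- bonesr:::set_path(m2$params, pth, W2)
    num <- (mse_loss(nf(m2, x)$out, t) - cl$value) / eps
    expect_equal(bonesr:::get_path(g, pth)[i], num, tolerance = 1e-4)
  }
})
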