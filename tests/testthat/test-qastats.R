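test_that("a blur-free phantom reads MTF ~ 1 at every group frequency", {
  ph <- make_line_pair_phantom(line_pair_spec(noise_sd = 0, slices = 2))
  curve <- mtf_from_line_pairs(ph$volume, ph$rois)
  expect_true(all(curve$samples$mtf > 0.95 & curve$samples$mtf < 1.05))
  expect_true(all(curve$samples$ci_halfwidth == 0))
})

test_that("a uniform phantom without bars has zero modulation", {
  ph2 <- make_line_pair_phantom(line_pair_spec(noise_sd = 0, slices = 2))
  # overwrite every group band with the background level
  for (g in ph2$rois$groups)
    ph2$volume$data[, g$rows[1]:g$rows[2], ] <- 0.2
  curve <- mtf_from_line_pairs(ph2$volume, ph2$rois)
  expect_true(all(curve$samples$mtf == 0))
})

test_that("Gaussian blur reproduces the analytic MTF within 0.05 per group", {
  ph <- make_line_pair_phantom(line_pair_spec(noise_sd = 0, slices = 2))
  for (sig in c(0.8, 1.0)) {
    blurred <- ph$volume
    for (s in seq_len(dim(blurred$data)[1]))
      blurred$data[s, , ] <- gaussian_blur(blurred$data[s, , ], c(0, sig))
    curve <- mtf_from_line_pairs(blurred, ph$rois)
    f_px <- curve$samples$freq_lp_cm * 200 / 1e4
    expect_lt(max(abs(curve$samples$mtf - exp(-2 * pi^2 * sig^2 * f_px^2))),
              0.05)
  }
})

test_that("stronger blur degrades the MTF monotonically", {
  ph <- make_line_pair_phantom(line_pair_spec(noise_sd = 0, slices = 2))
  sigmas <- c(0.5, 1.0, 1.5)
  curves <- lapply(sigmas, function(sig) {
    b <- ph$volume
    for (s in seq_len(dim(b$data)[1]))
      b$data[s, , ] <- gaussian_blur(b$data[s, , ], c(0, sig))
    mtf_from_line_pairs(b, ph$rois)
  })
  for (i in 1:2) {
    expect_true(all(curves[[i + 1]]$samples$mtf <=
                      curves[[i]]$samples$mtf + 1e-9))
  }
  # the mildest blur never falls to 0.5 inside the sampled band ("not
  # reached"); where both readouts exist they must be ordered
  expect_true(is.na(curves[[1]]$mtf50_lp_cm))
  expect_lte(curves[[3]]$mtf50_lp_cm, curves[[2]]$mtf50_lp_cm + 1e-9)
})

test_that("max-intensity normalization is invariant to global rescaling", {
  ph <- make_line_pair_phantom(line_pair_spec(noise_sd = 0, slices = 2))
  b <- ph$volume
  for (s in seq_len(dim(b$data)[1]))
    b$data[s, , ] <- gaussian_blur(b$data[s, , ], c(0, 1))
  c1 <- mtf_from_line_pairs(b, ph$rois, normalization = "max_intensity")
  b2 <- b; b2$data <- b2$data * 0.5
  c2 <- mtf_from_line_pairs(b2, ph$rois, normalization = "max_intensity")
  expect_equal(c1$samples$mtf, c2$samples$mtf, tolerance = 1e-9)
  expect_equal(max(c1$samples$mtf), 1)
  # material-pair and max-intensity differ by one positive scalar
  c3 <- mtf_from_line_pairs(b, ph$rois, normalization = "material_pair")
  ratio <- c3$samples$mtf / c1$samples$mtf
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("MTF percentile readouts interpolate and detect non-crossings", {
  s <- data.frame(freq_lp_cm = c(2, 4, 8), mtf = c(1.0, 0.5, 0.1))
  expect_equal(mtf_percentiles(s, c(0.5, 0.1)), c(4, 8))
  s2 <- data.frame(freq_lp_cm = c(2, 6), mtf = c(0.8, 0.4))
  expect_equal(mtf_percentiles(s2, 0.5), 5.0)
  flat <- data.frame(freq_lp_cm = c(2, 4, 8), mtf = c(0.9, 0.9, 0.9))
  expect_true(is.na(mtf_percentiles(flat, 0.1)))
  # the cubic-polynomial trendline readout stays close to linear on smooth data
  f <- seq(2, 10, length.out = 6)
  sm <- data.frame(freq_lp_cm = f, mtf = exp(-0.05 * f^2))
  lin <- mtf_percentiles(sm, 0.5, "linear")
  ply <- mtf_percentiles(sm, 0.5, "poly3")
  expect_lt(abs(lin - ply), 0.3)
})

test_that("Pearson r matches the covariance formula and Fisher interval", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  with_seed(10, {
    a <- rnorm(10); b <- rnorm(10)
    r_hand <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    pr <- pearson_r(a, b)
    expect_equal(pr$r, r_hand, tolerance = 1e-12)
    z <- atanh(pr$r)
    expect_equal(pr$ci95, tanh(z + c(-1.96, 1.96) / sqrt(7)))
  })
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("Bland-Altman reports bias and 1.96-sd limits of agreement", {
  a <- c(1, 2, 3, 4)
  expect_equal(bland_altman(a, a), list(bias = 0, sd = 0, loa_low = 0,
                                        loa_high = 0))
  r <- bland_altman(a + 5, a)
  expect_equal(r$bias, 5); expect_equal(r$sd, 0)
  with_seed(4, {
    x <- rnorm(12); y <- rnorm(12)
    r2 <- bland_altman(x, y)
    expect_equal(r2$bias, mean(x - y))
    expect_equal(r2$loa_high, mean(x - y) + 1.96 * sd(x - y))
  })
})

test_that("weighted kappa matches the hand-expanded toy table", {
  r1 <- rep(1:2, c(5, 5)); r2 <- r1
  expect_equal(weighted_kappa(r1, r2, 2)$kappa, 1)
  # table o = [[.4,.1],[.1,.4]]: po = .8, pe = .5 -> kappa = .6 (binary case,
  # linear weights reduce to the unweighted formula)
  r1 <- rep(c(1, 1, 2, 2), c(4, 1, 1, 4))
  r2 <- rep(c(1, 2, 1, 2), c(4, 1, 1, 4))
  k <- weighted_kappa(r1, r2, 2)
  expect_equal(k$kappa, (0.8 - 0.5) / (1 - 0.5))
  # independent ratings concentrate near zero
  with_seed(60, {
    a <- sample(1:4, 4000, TRUE); b <- sample(1:4, 4000, TRUE)
    expect_lt(abs(weighted_kappa(a, b, 4)$kappa), 0.05)
  })
  expect_error(weighted_kappa(rep(1, 5), rep(1, 5), 4), "degenerate")
})

test_that("Wilcoxon signed-rank uses the exact null and Bonferroni scaling", {
  b <- c(1, 2, 3, 4, 5); a <- b + c(1, 2, 3, 4, 5)  # distinct positive diffs
  w <- wilcoxon_signed_rank(a, b)
  expect_equal(w$p_value, 2 / 32)  # all-positive signs, two-sided exact
  w3 <- wilcoxon_signed_rank(a, b, bonferroni_m = 3)
  expect_equal(w3$p_adjusted, 3 * 2 / 32)
  expect_equal(wilcoxon_signed_rank(a, b, bonferroni_m = 100)$p_adjusted, 1)
  expect_error(wilcoxon_signed_rank(a, a), "zero")
  # ties fall back to the corrected normal approximation and stay in (0, 1)
  with_seed(2, {
    x <- sample(1:3, 30, TRUE); y <- sample(1:3, 30, TRUE)
    keep <- x != y
    if (sum(keep) > 5) {
      p <- wilcoxon_signed_rank(x, y)$p_value
      expect_gt(p, 0); expect_lte(p, 1)
    }
  })
})
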