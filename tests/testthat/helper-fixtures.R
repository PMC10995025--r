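# Shared fixtures and independent brute-force oracles. The oracles differ
# structurally from the implementation paths they check: Otsu by explicit
# threshold enumeration, local thickness by exhaustive inscribed-sphere
# search over pairwise distances, statistics by direct formula expansion.

random_uint8_volume <- function(dims, seed) {
  with_seed(seed, new_volume(array(sample(0:255, prod(dims), TRUE), dims),
                             50, "uint8"))
}

random_mask <- function(dims, seed, p = 0.4, smooth = 1) {
  with_seed(seed, {
    f <- gaussian_blur(array(rnorm(prod(dims)), dims), smooth)
    f > quantile(f, 1 - p)
  })
}

# Brute-force Otsu: maximize between-class variance over every cut of the
# 256-bin histogram by explicit looping.
otsu_brute <- function(x01) {
  nb <- 256L
  bin <- pmin(nb, floor(as.vector(x01) * nb) + 1L)
  h <- tabulate(bin, nbins = nb)
  p <- h / sum(h)
  centers <- (seq_len(nb) - 0.5) / nb
  best <- -Inf; best_t <- NA
  for (t in 1:(nb - 1L)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:t] * centers[1:t]) / w0
    mu1 <- sum(p[(t + 1):nb] * centers[(t + 1):nb]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-15) { best <- sb; best_t <- t }
  }
  best_t / nb
}

# Brute-force local thickness: for every phase voxel c compute the squared
# distance to the nearest background voxel by full enumeration, then assign
# every voxel the diameter of the largest sphere (strictly) covering it.
thickness_brute <- function(mask) {
  d <- dim(mask)
  idx_fg <- which(mask)
  idx_bg <- which(!mask)
  co_fg <- arrayInd(idx_fg, d)
  co_bg <- arrayInd(idx_bg, d)
  r2 <- vapply(seq_along(idx_fg), function(i) {
    dif <- sweep(co_bg, 2, co_fg[i, ])
    min(rowSums(dif^2))
  }, numeric(1))
  th <- numeric(length(idx_fg))
  d2 <- as.matrix(dist(co_fg))^2
  for (i in seq_along(idx_fg)) {
    covered <- d2[, i] + 0.5 < r2
    th[i] <- 2 * sqrt(max(r2[covered]))
  }
  out <- array(0, d)
  out[idx_fg] <- th
  out
}

# Small trabecular grayscale fixture shared across tests.
tiny_trabecular <- function(seed = 3, noise = 0, extents = c(24, 24, 24)) {
  make_trabecular(trabecular_spec(extents = extents, noise_sd = noise,
                                  blur_sd_vox = 0, seed = seed),
                  thickness_reference = FALSE)
}
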