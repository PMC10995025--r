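# Technical image-quality analysis and agreement statistics: line-pair MTF
# by the noise-corrected ROI standard-deviation method, MTF50/MTF10
# readouts, and the comparison statistics used to judge super-resolved
# against reference measurements.

roi_pixels <- function(sl, roi) sl[roi$rows[1]:roi$rows[2],
                                   roi$cols[1]:roi$cols[2]]

# Standard deviation of an ideal 50%-duty square wave of half-contrast M0,
# rendered with pixel-area integration at frequency f (cycles/pixel): the
# odd harmonics carry amplitude 4*M0/(pi*k), each attenuated by the pixel
# aperture sinc(k f); aliased power remains in the variance, so the series
# is summed without a Nyquist cutoff (it converges as 1/k^4).
square_wave_sd <- function(f_px, M0 = 1, kmax = 399L) {
  k <- seq(1L, kmax, by = 2L)
  sc <- ifelse(k * f_px == 0, 1, sin(pi * k * f_px) / (pi * k * f_px))
  M0 * sqrt((8 / pi^2) * sum(sc^2 / k^2))
}

#' Modulation transfer function from line-pair bar groups
#'
#' Per slice and group, the modulation is the noise-corrected standard
#' deviation `sqrt(max(sd(ROI)^2 - sd(noise ROI)^2, 0))`. Two conversions to
#' sine-wave MTF are provided: `"calibrated"` (default) divides by the
#' analytic sd of an ideal pixel-integrated square wave at the group
#' frequency and the material contrast, so a blur-free phantom reads exactly
#' 1 at every frequency; `"droege"` is the classical single-constant
#' `pi*sqrt(2)/4 * M / M0` form. Under `material_pair` normalization the
#' contrast scale `M0` is half the absolute difference of the two material
#' ROI means; under `max_intensity` the curve is afterwards rescaled so its
#' maximum is 1 (making the readout invariant to global intensity
#' rescaling, the fallback when grayscale calibration is distorted).
#' Slice-wise values give a t-based 95% confidence half-width per group.
#'
#' @param vol phantom volume.
#' @param rois a `roi_set` (as returned by [make_line_pair_phantom()]):
#'   `groups` (with `freq_lp_cm`), `materials` (>= 2), `noise`.
#' @param freqs optional frequency vector overriding the ROI annotations.
#' @param normalization "material_pair" or "max_intensity".
#' @param conversion "calibrated" or "droege".
#' @param pixel_size_um in-plane pixel size; taken from the volume when
#'   omitted.
#' @return an `mtf_curve`: data.frame `samples` (freq_lp_cm, mtf,
#'   ci_halfwidth), the normalization/conversion tags, and `mtf50_lp_cm`,
#'   `mtf10_lp_cm` (linear-interpolated readouts; NA when not reached).
#' @export
mtf_from_line_pairs <- function(vol, rois, freqs = NULL,
                                normalization = c("material_pair",
                                                  "max_intensity"),
                                conversion = c("calibrated", "droege"),
                                pixel_size_um = NULL) {
  stopifnot(is_volume(vol))
  normalization <- match.arg(normalization)
  conversion <- match.arg(conversion)
  pixel_size_um <- pixel_size_um %||% vol$voxel_size_um[3]
  freqs <- freqs %||% vapply(rois$groups, `[[`, numeric(1), "freq_lp_cm")
  if (length(freqs) != length(rois$groups))
    stop("need one frequency per group ROI")
  if (is.null(rois$noise)) stop("noise ROI is required")
  x <- vol$data
  ns <- dim(x)[1]
  ng <- length(freqs)
  f_px <- freqs * pixel_size_um / 1e4  # lp/cm -> cycles per pixel
  if (any(f_px > 0.5)) stop("group frequency above the Nyquist limit")
  mtf_sl <- matrix(0, ns, ng)
  for (s in seq_len(ns)) {
    sl <- x[s, , ]
    sd_noise <- sd(roi_pixels(sl, rois$noise))
    mA <- mean(roi_pixels(sl, rois$materials[[1]]))
    mB <- mean(roi_pixels(sl, rois$materials[[2]]))
    M0 <- abs(mA - mB) / 2
    if (M0 <= 0) stop("zero material contrast: M0 undefined")
    for (g in seq_len(ng)) {
      sd_g <- sd(roi_pixels(sl, rois$groups[[g]]))
      M <- sqrt(max(sd_g^2 - sd_noise^2, 0))
      mtf_sl[s, g] <- if (conversion == "droege") (pi * sqrt(2) / 4) * M / M0
                      else M / square_wave_sd(f_px[g], M0)
    }
  }
  m <- colMeans(mtf_sl)
  ci <- if (ns > 1) qt(0.975, ns - 1) * apply(mtf_sl, 2, sd) / sqrt(ns)
        else rep(0, ng)
  if (normalization == "max_intensity") {
    sc <- max(m)
    if (sc <= 0) stop("flat curve cannot be max-normalized")
    m <- m / sc; ci <- ci / sc
  }
  curve <- structure(
    list(samples = data.frame(freq_lp_cm = freqs, mtf = m, ci_halfwidth = ci),
         normalization = normalization, conversion = conversion),
    class = "mtf_curve")
  curve$mtf50_lp_cm <- mtf_percentiles(curve, 0.5)
  curve$mtf10_lp_cm <- mtf_percentiles(curve, 0.1)
  curve
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("<mtf_curve> %s/%s; MTF50 %s, MTF10 %s lp/cm\n",
              x$normalization, x$conversion,
              ifelse(is.na(x$mtf50_lp_cm), "not reached",
                     sprintf("%.2f", x$mtf50_lp_cm)),
              ifelse(is.na(x$mtf10_lp_cm), "not reached",
                     sprintf("%.2f", x$mtf10_lp_cm))))
  print(x$samples)
  invisible(x)
}

#' Frequencies at which an MTF curve crosses given levels
#'
#' `"linear"` interpolates between the bracketing samples of the first
#' crossing from the low-frequency side (exact when a sample hits the
#' level); `"poly3"` reads the crossing off a fitted third-order polynomial
#' trendline. Levels never crossed give NA ("not reached").
#'
#' @param curve an `mtf_curve` or a data.frame with `freq_lp_cm`, `mtf`.
#' @param levels MTF levels, default `c(0.5, 0.1)`.
#' @param method "linear" or "poly3".
#' @return numeric vector of frequencies (lp/cm), NA where not reached.
#' @export
mtf_percentiles <- function(curve, levels = c(0.5, 0.1),
                            method = c("linear", "poly3")) {
  method <- match.arg(method)
  s <- if (inherits(curve, "mtf_curve")) curve$samples else curve
  if (nrow(s) < 2L) stop("need at least two MTF samples")
  f <- s$freq_lp_cm; m <- s$mtf
  vapply(levels, function(lv) {
    if (method == "linear") {
      j <- which(m <= lv)
      j <- j[j > 1L | m[j] == lv]
      if (!length(j)) return(NA_real_)
      j <- j[1]
      if (m[j] == lv) return(f[j])
      if (j == 1L || m[j - 1L] <= lv) return(NA_real_)
      f[j - 1L] + (m[j - 1L] - lv) / (m[j - 1L] - m[j]) * (f[j] - f[j - 1L])
    } else {
      fit <- lm(m ~ poly(f, 3, raw = TRUE))
      grid <- seq(min(f), max(f), length.out = 2000L)
      pv <- predict(fit, data.frame(f = grid))
      j <- which(pv <= lv & seq_along(grid) > 1L)
      if (!length(j)) return(NA_real_)
      j <- j[1]
      approx(c(pv[j - 1L], pv[j]), c(grid[j - 1L], grid[j]), xout = lv)$y
    }
  }, numeric(1))
}

#' Pearson correlation with a Fisher-z 95% confidence interval
#'
#' @param x,y paired numeric vectors, n >= 3 (n >= 4 for the interval).
#' @return list with `r` and `ci95` (`c(lo, hi)`; NA when n < 4).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  n <- length(x)
  ci <- if (n >= 4L && abs(r) < 1) {
    z <- atanh(r)
    tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
  } else c(NA_real_, NA_real_)
  list(r = r, ci95 = ci)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`: bias = mean(d), limits of agreement
#' bias +/- 1.96 sd(d) (sample sd, n-1 denominator).
#'
#' @param a,b paired measurement vectors.
#' @return list with `bias`, `sd`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need n >= 2")
  d <- a - b
  bias <- mean(d); s <- sd(d)
  list(bias = bias, sd = s, loa_low = bias - 1.96 * s,
       loa_high = bias + 1.96 * s)
}

#' Linearly weighted Cohen's kappa with an asymptotic 95% CI
#'
#' Disagreement weights `|i - j| / (n_levels - 1)`;
#' `kappa = 1 - sum(w o) / sum(w e)` with observed proportions `o` and
#' chance proportions `e` from the marginal outer product. The variance is
#' the standard large-sample form (Fleiss, Cohen & Everitt).
#'
#' @param r1,r2 integer ratings in `1..n_levels`.
#' @param n_levels number of ordinal levels.
#' @return list with `kappa` and `ci95`.
#' @export
weighted_kappa <- function(r1, r2, n_levels = max(c(r1, r2))) {
  if (length(r1) != length(r2)) stop("length mismatch")
  if (any(c(r1, r2) < 1L) || any(c(r1, r2) > n_levels))
    stop("ratings must lie in 1..n_levels")
  n <- length(r1)
  L <- n_levels
  o <- table(factor(r1, levels = 1:L), factor(r2, levels = 1:L)) / n
  o <- unclass(o)
  pi_ <- rowSums(o); pj <- colSums(o)
  e <- outer(pi_, pj)
  v <- 1 - abs(outer(1:L, 1:L, "-")) / (L - 1)  # agreement weights
  po <- sum(v * o); pe <- sum(v * e)
  if (1 - pe < 1e-12)
    stop("degenerate marginals: chance agreement is 1, kappa undefined")
  kap <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample variance
  vi <- as.vector(v %*% pj)   # row-wise expected weight, sum_j p+j v_ij
  vj <- as.vector(pi_ %*% v)  # col-wise expected weight, sum_i pi+ v_ij
  term <- outer(vi, vj, function(a, b) a + b)
  s2 <- (sum(o * (v - term * (1 - kap))^2) - (kap - pe * (1 - kap))^2) /
    (n * (1 - pe)^2)
  se <- sqrt(max(s2, 0))
  list(kappa = kap, ci95 = kap + c(-1.96, 1.96) * se)
}

#' Wilcoxon signed-rank test with Bonferroni correction
#'
#' Zero differences are dropped; the exact null distribution is used for
#' n <= 25 without ties, otherwise the tie-corrected normal approximation
#' (via `stats::wilcox.test`). The adjusted p-value is `min(1, m * p)`.
#'
#' @param a,b paired vectors.
#' @param bonferroni_m number of comparisons in the family (default 1).
#' @return list with `statistic` (V), `p_value`, `p_adjusted`, `n_effective`.
#' @export
wilcoxon_signed_rank <- function(a, b, bonferroni_m = 1L) {
  if (length(a) != length(b)) stop("length mismatch")
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       p_adjusted = min(1, bonferroni_m * wt$p.value),
       n_effective = length(d))
}
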