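# Whole-volume inference: tiles are predicted over a sliding window and
# blended with a Gaussian weight map so each output voxel is a convex
# combination of overlapping tile predictions (weights cancel exactly for
# consistent tiles, so constants pass through unchanged). The two
# non-learned benchmarks (tricubic interpolation and the filtering pipeline)
# live here too.

#' Sliding-window configuration
#'
#' @param window_lr input-grid window side (default 16).
#' @param step_lr input-grid step (default 8; must be <= window).
#' @param weight_sigma_out sd of the Gaussian blending weights on the output
#'   grid; default `window_lr * 4 / 4` = 16 output pixels, concentrating
#'   mass centrally while keeping corners positive.
#' @param plane "axial", "coronal", "sagittal" (2D models) or "average3".
#' @return a `sliding_window_config`.
#' @export
sliding_window_config <- function(window_lr = 16L, step_lr = 8L,
                                  weight_sigma_out = window_lr * 4 / 4,
                                  plane = "axial") {
  if (step_lr > window_lr) stop("step must be <= window")
  structure(list(window_lr = as.integer(window_lr),
                 step_lr = as.integer(step_lr),
                 weight_sigma_out = weight_sigma_out, plane = plane),
            class = "sliding_window_config")
}

#' Gaussian blending weight map
#'
#' Separable Gaussian centred at the tile centre (distance measured from the
#' continuous centre, so even-sized windows peak just below 1), floored at
#' 1e-4 so accumulated weights are strictly positive everywhere.
#'
#' @param window_out output tile side.
#' @param sigma Gaussian sd in output pixels.
#' @param dims 2 or 3.
#' @return a `window_out`^dims array with values in (0, 1].
#' @export
gaussian_weight_map <- function(window_out, sigma, dims = 2L) {
  if (sigma <= 0) stop("sigma must be positive")
  d <- seq_len(window_out) - (window_out + 1) / 2
  w1 <- exp(-d^2 / (2 * sigma^2))
  w <- if (dims == 2L) outer(w1, w1) else outer(outer(w1, w1), w1)
  pmax(array(w, rep(window_out, dims)), 1e-4)
}

tile_starts <- function(n, w, s) {
  np <- max(1L, ceiling((n - w) / s) + 1L)
  pad <- (np - 1L) * s + w - n
  list(starts = seq(0L, np - 1L) * s + 1L, pad = pad)
}

pad_reflect_2d <- function(m, p1, p2) {
  if (p1 > 0) m <- m[reflect_index(seq_len(nrow(m) + p1), nrow(m)), , drop = FALSE]
  if (p2 > 0) m <- m[, reflect_index(seq_len(ncol(m) + p2), ncol(m)), drop = FALSE]
  m
}

# Blend one 2D slice: predict tiles and accumulate weighted outputs.
sr_slice <- function(model, sl, cfg, info_base = list()) {
  w <- cfg$window_lr; s <- cfg$step_lr
  t1 <- tile_starts(nrow(sl), w, s)
  t2 <- tile_starts(ncol(sl), w, s)
  slp <- pad_reflect_2d(sl, t1$pad, t2$pad)
  wout <- 4L * w
  wm <- gaussian_weight_map(wout, cfg$weight_sigma_out, 2L)
  H <- 4L * nrow(slp); W <- 4L * ncol(slp)
  acc <- matrix(0, H, W); wac <- matrix(0, H, W)
  for (y in t1$starts) for (x in t2$starts) {
    tile <- slp[y:(y + w - 1L), x:(x + w - 1L)]
    info <- c(info_base, list(origin = c(y, x)))
    pred <- predict_tile(model, tile, info)
    if (!all(dim(pred) == wout)) stop("model did not return a x4 tile")
    hy <- 4L * (y - 1L) + 1L; hx <- 4L * (x - 1L) + 1L
    ys <- hy:(hy + wout - 1L); xs <- hx:(hx + wout - 1L)
    acc[ys, xs] <- acc[ys, xs] + pred * wm
    wac[ys, xs] <- wac[ys, xs] + wm
  }
  (acc / wac)[seq_len(4L * nrow(sl)), seq_len(4L * ncol(sl)), drop = FALSE]
}

#' Gaussian-blended sliding-window super-resolution
#'
#' For 2D models, every slice perpendicular to `cfg$plane` is processed
#' in-plane (output extents x4 in-plane, slice extent unchanged); for 3D
#' models the window slides in 3D and all extents grow x4. Volumes are
#' reflection-padded so the window grid covers the borders; the padding is
#' cropped from the output. Every output voxel is
#' sum(weight * prediction) / sum(weight).
#'
#' @param vol input volume (float01).
#' @param model a trained `bsr_model` or stub.
#' @param cfg a [sliding_window_config()].
#' @return the super-resolved volume.
#' @export
sliding_window_sr <- function(vol, model, cfg = sliding_window_config()) {
  stopifnot(is_volume(vol))
  if ((inherits(model, "bsr_model") && model$config$dims == 3L) ||
      identical(cfg$plane, "3d")) {
    return(sr_volume_3d(vol, model, cfg))
  }
  x <- vol$data
  ax <- plane_axis(cfg$plane)
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  out <- array(0, c(dp[1], 4L * dp[2], 4L * dp[3]))
  for (s in seq_len(dp[1]))
    out[s, , ] <- sr_slice(model, xp[s, , ], cfg,
                           info_base = list(slice = s, plane = ax))
  out <- aperm(out, order(perm))
  vox <- vol$voxel_size_um
  vox[setdiff(1:3, ax)] <- vox[setdiff(1:3, ax)] / 4
  new_volume(clip01(out), vox, "float01", vol$meta)
}

sr_volume_3d <- function(vol, model, cfg) {
  if (inherits(model, "bsr_model") && model$config$dims != 3L)
    stop("3D sliding window requires a 3D model")
  x <- vol$data
  w <- cfg$window_lr; s <- cfg$step_lr
  ts <- lapply(dim(x), tile_starts, w = w, s = s)
  # reflect-pad all axes
  for (a in 1:3) {
    if (ts[[a]]$pad > 0) {
      idx <- reflect_index(seq_len(dim(x)[a] + ts[[a]]$pad), dim(x)[a])
      x <- slice_axis(x, a, idx)
    }
  }
  wout <- 4L * w
  wm <- gaussian_weight_map(wout, cfg$weight_sigma_out, 3L)
  dp <- dim(x)
  acc <- array(0, 4L * dp); wac <- array(0, 4L * dp)
  for (z in ts[[1]]$starts) for (y in ts[[2]]$starts) for (xx in ts[[3]]$starts) {
    tile <- x[z:(z + w - 1L), y:(y + w - 1L), xx:(xx + w - 1L)]
    pred <- predict_tile(model, tile, list(origin = c(z, y, xx)))
    hz <- 4L * (z - 1L) + 1L; hy <- 4L * (y - 1L) + 1L; hx <- 4L * (xx - 1L) + 1L
    zs <- hz:(hz + wout - 1L); ys <- hy:(hy + wout - 1L); xs <- hx:(hx + wout - 1L)
    acc[zs, ys, xs] <- acc[zs, ys, xs] + pred * wm
    wac[zs, ys, xs] <- wac[zs, ys, xs] + wm
  }
  out <- (acc / wac)[seq_len(4L * dim(vol$data)[1]),
                     seq_len(4L * dim(vol$data)[2]),
                     seq_len(4L * dim(vol$data)[3])]
  new_volume(clip01(out), vol$voxel_size_um / 4, "float01", vol$meta)
}

#' Average of 2D predictions over the three orthogonal planes
#'
#' Each plane's slice stack is super-resolved in-plane, its slice axis is
#' resampled x4 by cubic interpolation onto the common isotropic grid, and
#' the three volumes are averaged voxel-wise.
#'
#' @param vol input volume.
#' @param model a 2D model (or stub).
#' @param cfg a [sliding_window_config()]; its `plane` field is ignored.
#' @return the isotropically x4 super-resolved volume.
#' @export
orthogonal_average <- function(vol, model, cfg = sliding_window_config()) {
  if (inherits(model, "bsr_model") && model$config$dims != 2L)
    stop("orthogonal_average requires a 2D model")
  acc <- 0
  for (plane in c("axial", "coronal", "sagittal")) {
    cfg$plane <- plane
    sr <- sliding_window_sr(vol, model, cfg)
    ax <- plane_axis(plane)
    nd <- dim(sr$data); nd[ax] <- nd[ax] * 4L
    up <- resample_array(sr$data, nd, method = "cubic", antialias = FALSE)
    acc <- acc + up
  }
  new_volume(clip01(acc / 3), vol$voxel_size_um / 4, "float01", vol$meta)
}

#' Tricubic interpolation benchmark
#'
#' Separable Catmull-Rom cubic interpolation to the x4 grid on all three
#' axes, clipped to `[0, 1]`.
#'
#' @param vol input volume (extents >= 2 per axis).
#' @param factor upscale factor (default 4).
#' @return the interpolated volume.
#' @export
tricubic_upscale <- function(vol, factor = 4L) {
  stopifnot(is_volume(vol))
  if (any(dim(vol$data) < 2L)) stop("extents must be >= 2 per axis")
  out <- resample_array(vol$data, dim(vol$data) * as.integer(factor),
                        method = "cubic", antialias = FALSE)
  new_volume(clip01(out), vol$voxel_size_um / factor, "float01", vol$meta)
}

#' Conventional image-processing benchmark
#'
#' Perona-Malik anisotropic diffusion (exponential conductance), percentile
#' contrast stretching, then a median filter, in that order — the classical
#' enhancement chain used as a non-learned comparison.
#'
#' @param vol float01 volume.
#' @param iterations,kappa,dt diffusion iterations, conductance scale and
#'   time step (defaults 10, 30/255, 0.1).
#' @param stretch_percentiles contrast-stretch percentiles (default 2, 98);
#'   a degenerate range maps to 0.
#' @param median_size median window (default 3).
#' @return the enhanced volume.
#' @export
conventional_enhance <- function(vol, iterations = 10L, kappa = 30 / 255,
                                 dt = 0.1, stretch_percentiles = c(2, 98),
                                 median_size = 3L) {
  stopifnot(is_volume(vol))
  x <- vol$data
  d <- dim(x)
  for (it in seq_len(iterations)) {
    upd <- 0
    for (a in 1:3) {
      if (d[a] < 2L) next
      n <- d[a]
      fwd <- slice_axis(x, a, c(2:n, n)) - x       # forward difference
      bwd <- slice_axis(x, a, c(1, 1:(n - 1))) - x # backward difference
      upd <- upd + exp(-(fwd / kappa)^2) * fwd + exp(-(bwd / kappa)^2) * bwd
    }
    x <- x + dt * upd
  }
  rng <- quantile(x, stretch_percentiles / 100, names = FALSE)
  x <- if (rng[2] <= rng[1]) array(0, d)
       else clip01((x - rng[1]) / (rng[2] - rng[1]))
  x <- median_filter(x, median_size)
  new_volume(clip01(x), vol$voxel_size_um, "float01", vol$meta)
}
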