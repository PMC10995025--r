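# Paired stochastic augmentation. Geometric transforms are sampled once and
# applied with identical parameters to both members of a pair (translations
# scaled x4 on the target grid); grayscale brightness/contrast also touch
# both (the pair must depict the same tissue), while blur degrades only the
# input. Rotations are right-angle multiples plus optional small-angle
# bilinear rotations with reflect padding.

#' Augmentation policy
#'
#' @param p_flip per-axis flip probabilities (length = spatial dims of the
#'   patches; in 3D the first entry is the slice axis).
#' @param p_rot90 probability of a random in-plane quarter-turn.
#' @param small_angle_deg half-range of small in-plane rotations (degrees);
#'   0 disables them.
#' @param p_small_angle probability of applying a small-angle rotation.
#' @param translate_vox maximum in-plane translation on the input grid
#'   (voxels); the target is translated by four times the same offset.
#' @param brightness additive range (float01 units), e.g. `c(-0.1, 0.1)`.
#' @param contrast multiplicative range about the patch mean.
#' @param p_blur probability of blurring the input patch.
#' @param blur_sd range of the input blur sd (voxels).
#' @param crop_lr network input side for [crop_pad_to_net()] (16 by default;
#'   the target window is four times that).
#' @return an `augment_policy` list. `augment_policy_off()` returns the
#'   identity policy.
#' @export
augment_policy <- function(p_flip = c(0, 0.5, 0.5), p_rot90 = 0.5,
                           small_angle_deg = 10, p_small_angle = 0.25,
                           translate_vox = 2, brightness = c(-0.05, 0.05),
                           contrast = c(0.9, 1.1), p_blur = 0.25,
                           blur_sd = c(0.2, 1.0), crop_lr = 16L) {
  if (any(p_flip < 0 | p_flip > 1) || p_rot90 < 0 || p_rot90 > 1 ||
      p_small_angle < 0 || p_small_angle > 1 || p_blur < 0 || p_blur > 1)
    stop("probabilities must lie in [0, 1]")
  structure(list(p_flip = p_flip, p_rot90 = p_rot90,
                 small_angle_deg = small_angle_deg,
                 p_small_angle = p_small_angle, translate_vox = translate_vox,
                 brightness = brightness, contrast = contrast, p_blur = p_blur,
                 blur_sd = blur_sd, crop_lr = as.integer(crop_lr)),
            class = "augment_policy")
}

#' @rdname augment_policy
#' @export
augment_policy_off <- function(crop_lr = 16L) {
  augment_policy(p_flip = c(0, 0, 0), p_rot90 = 0, small_angle_deg = 0,
                 p_small_angle = 0, translate_vox = 0, brightness = c(0, 0),
                 contrast = c(1, 1), p_blur = 0, blur_sd = c(0, 0),
                 crop_lr = crop_lr)
}

flip_axis <- function(x, axis) {
  d <- dim(x)
  idx <- rev(seq_len(d[axis]))
  switch(length(d),
    NULL,
    if (axis == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE],
    switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
           x[, , idx, drop = FALSE]))
}

rot90_mat <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m[nrow(m):1L, , drop = FALSE])
  m
}

# Bilinear sampling of matrix `m` after rotating by `theta` about the centre
# and translating by (dy, dx); reflect padding outside the support.
affine_sample <- function(m, theta, dy = 0, dx = 0) {
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(rep(seq_len(W), each = H), H, W) - cx
  ct <- cos(theta); st <- sin(theta)
  ys <- ct * yy - st * xx + cy - dy
  xs <- st * yy + ct * xx + cx - dx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  g <- function(yi, xi) m[cbind(reflect_index(as.vector(yi), H),
                                reflect_index(as.vector(xi), W))]
  v <- (1 - fy) * (1 - fx) * g(y0, x0) + (1 - fy) * fx * g(y0, x0 + 1) +
    fy * (1 - fx) * g(y0 + 1, x0) + fy * fx * g(y0 + 1, x0 + 1)
  matrix(v, H, W)
}

apply_inplane <- function(arr, fn) {
  if (length(dim(arr)) == 2L) return(fn(arr))
  for (s in seq_len(dim(arr)[1])) arr[s, , ] <- fn(arr[s, , ])
  arr
}

#' Apply a sampled augmentation to a patch pair
#'
#' Draws transform parameters from the policy using the current RNG state
#' (seed externally with [with_seed()] for reproducibility) and applies them
#' consistently to both patches. Outputs are clipped to `[0, 1]`.
#'
#' @param pair a `patch_pair`.
#' @param policy an [augment_policy()].
#' @return the augmented `patch_pair`.
#' @export
augment_pair <- function(pair, policy) {
  stopifnot(inherits(pair, "patch_pair"), inherits(policy, "augment_policy"))
  lr <- pair$lr; hr <- pair$hr
  nd <- length(dim(lr))
  axes <- seq_len(nd)
  pf <- rep(policy$p_flip, length.out = nd)
  for (a in axes) if (runif(1) < pf[a]) {
    lr <- flip_axis(lr, a); hr <- flip_axis(hr, a)
  }
  if (runif(1) < policy$p_rot90) {
    k <- sample(1:3, 1)
    lr <- apply_inplane(lr, function(m) rot90_mat(m, k))
    hr <- apply_inplane(hr, function(m) rot90_mat(m, k))
    if (nd == 3L) {  # square in-plane patches keep their shape under rot90
      stopifnot(dim(lr)[2] == dim(lr)[3])
    }
  }
  theta <- 0; dy <- 0; dx <- 0
  if (policy$small_angle_deg > 0 && runif(1) < policy$p_small_angle)
    theta <- runif(1, -policy$small_angle_deg, policy$small_angle_deg) * pi / 180
  if (policy$translate_vox > 0) {
    dy <- runif(1, -policy$translate_vox, policy$translate_vox)
    dx <- runif(1, -policy$translate_vox, policy$translate_vox)
  }
  if (theta != 0 || dy != 0 || dx != 0) {
    lr <- apply_inplane(lr, function(m) affine_sample(m, theta, dy, dx))
    hr <- apply_inplane(hr, function(m) affine_sample(m, theta, 4 * dy, 4 * dx))
  }
  b <- runif(1, policy$brightness[1], policy$brightness[2])
  cmul <- runif(1, policy$contrast[1], policy$contrast[2])
  if (b != 0 || cmul != 1) {
    lr <- (lr - 0.5) * cmul + 0.5 + b
    hr <- (hr - 0.5) * cmul + 0.5 + b
  }
  if (policy$p_blur > 0 && runif(1) < policy$p_blur) {
    sd <- runif(1, policy$blur_sd[1], policy$blur_sd[2])
    if (sd > 0) lr <- if (nd == 2L) gaussian_blur(lr, sd)
                else apply_inplane(lr, function(m) gaussian_blur(m, sd))
  }
  patch_pair(clip01(lr), clip01(hr), pair$sample_id, pair$patient_id,
             pair$origin)
}

pad_to <- function(x, target) {
  d <- dim(x)
  if (all(d >= target)) return(x)
  pads <- pmax(0L, target - d)
  lo <- pads %/% 2L
  out <- array(0, pmax(d, target))
  idx <- lapply(seq_along(d), function(a) lo[a] + seq_len(d[a]))
  if (length(d) == 2L) out[idx[[1]], idx[[2]]] <- x
  else out[idx[[1]], idx[[2]], idx[[3]]] <- x
  out
}

#' Random crop (or symmetric zero-pad) of a pair to the network size
#'
#' Crop offsets are drawn on the input grid; the target window starts at
#' four times the same offset, so the pair stays co-located. Patches smaller
#' than the crop are zero-padded symmetrically first (target padded by four
#' times as much).
#'
#' @param pair a `patch_pair`.
#' @param crop_lr input crop side (default from common network size, 16).
#' @param origin optional explicit crop origin (1-based, input grid) for
#'   deterministic cropping; random when NULL.
#' @return a `patch_pair` with lr `crop_lr`^d and hr `(4*crop_lr)`^d.
#' @export
crop_pad_to_net <- function(pair, crop_lr = 16L, origin = NULL) {
  stopifnot(inherits(pair, "patch_pair"))
  nd <- length(dim(pair$lr))
  tgt <- rep(as.integer(crop_lr), nd)
  lr <- pad_to(pair$lr, tgt)
  hr <- pad_to(pair$hr, 4L * tgt)
  d <- dim(lr)
  if (is.null(origin))
    origin <- vapply(seq_len(nd),
                     function(a) if (d[a] > tgt[a])
                       sample.int(d[a] - tgt[a] + 1L, 1L) else 1L, integer(1))
  o <- as.integer(origin); ho <- 4L * (o - 1L) + 1L
  idx <- lapply(seq_len(nd), function(a) o[a]:(o[a] + tgt[a] - 1L))
  hidx <- lapply(seq_len(nd), function(a) ho[a]:(ho[a] + 4L * tgt[a] - 1L))
  if (nd == 2L) {
    lrc <- lr[idx[[1]], idx[[2]]]
    hrc <- hr[hidx[[1]], hidx[[2]]]
  } else {
    lrc <- lr[idx[[1]], idx[[2]], idx[[3]]]
    hrc <- hr[hidx[[1]], hidx[[2]], hidx[[3]]]
  }
  patch_pair(lrc, hrc, pair$sample_id, pair$patient_id, o)
}
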