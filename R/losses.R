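# Loss functions for the three training recipes. Each returns the scalar
# value, and optionally the gradient with respect to the prediction (needed
# by the trainer); gradients are finite-difference-checked in the tests.

#' Mean-squared and mean-absolute error
#'
#' @param pred,target equal-shaped numeric arrays.
#' @param grad also return the gradient with respect to `pred`.
#' @return scalar, or `list(value, grad)` when `grad = TRUE`.
#' @export
mse_loss <- function(pred, target, grad = FALSE) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  dif <- pred - target
  v <- mean(dif^2)
  if (!grad) return(v)
  list(value = v, grad = 2 * dif / length(dif))
}

#' @rdname mse_loss
#' @export
mae_loss <- function(pred, target, grad = FALSE) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  dif <- pred - target
  v <- mean(abs(dif))
  if (!grad) return(v)
  list(value = v, grad = sign(dif) / length(dif))
}

#' Anisotropic total variation
#'
#' Mean absolute forward difference along each spatial axis, summed over
#' axes (axes of extent one contribute zero). The ramp image 0,1,2,3 as a
#' single row has TV exactly 1, fixing the normalization.
#'
#' @param pred numeric array with at least one spatial extent >= 2.
#' @param grad also return the gradient.
#' @return scalar TV (>= 0), or `list(value, grad)`.
#' @export
tv_loss <- function(pred, grad = FALSE) {
  d <- dim(pred)
  if (is.null(d)) d <- length(pred)
  if (max(d) < 2L) stop("total variation needs a spatial extent >= 2")
  v <- 0
  g <- if (grad) array(0, dim(pred)) else NULL
  for (a in seq_along(d)) {
    n <- d[a]
    if (n < 2L) next
    hi <- slice_axis(pred, a, 2L:n)
    lo <- slice_axis(pred, a, 1L:(n - 1L))
    dif <- hi - lo
    v <- v + mean(abs(dif))
    if (grad) {
      s <- sign(dif) / length(dif)
      g <- add_slice_axis(g, a, 2L:n, s)
      g <- add_slice_axis(g, a, 1L:(n - 1L), -s)
    }
  }
  if (!grad) return(v)
  list(value = v, grad = g)
}

slice_axis <- function(x, a, idx) {
  d <- dim(x)
  switch(length(d),
    x[idx],
    if (a == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE],
    switch(a, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
           x[, , idx, drop = FALSE]))
}

add_slice_axis <- function(x, a, idx, v) {
  d <- dim(x)
  if (length(d) == 2L) {
    if (a == 1L) x[idx, ] <- x[idx, ] + v else x[, idx] <- x[, idx] + v
  } else {
    if (a == 1L) x[idx, , ] <- x[idx, , ] + v
    else if (a == 2L) x[, idx, ] <- x[, idx, ] + v
    else x[, , idx] <- x[, , idx] + v
  }
  x
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over a Gaussian window (size 11, sd 1.5) with the
#' standard stabilizers K1 = 0.01, K2 = 0.03 and dynamic range 1 (float01
#' convention). Works on 2D and 3D arrays.
#'
#' @param pred,target equal-shaped arrays with values in `[0, 1]`.
#' @param window odd window size.
#' @param sigma Gaussian window sd.
#' @param K1,K2 stabilizer constants; `L` dynamic range.
#' @param grad also return the gradient of mean SSIM w.r.t. `pred`.
#' @return scalar in `[-1, 1]`, or `list(value, grad)`.
#' @export
ssim <- function(pred, target, window = 11L, sigma = 1.5, K1 = 0.01,
                 K2 = 0.03, L = 1, grad = FALSE) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  if (any(dim(pred) < window)) stop("window larger than image")
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  k <- gaussian_kernel1d(sigma, window)
  G <- function(x) { for (a in seq_along(dim(x))) x <- filter_axis(x, k, a); x }
  mx <- G(pred); my <- G(target)
  sxx <- G(pred^2) - mx^2
  syy <- G(target^2) - my^2
  sxy <- G(pred * target) - mx * my
  A1 <- 2 * mx * my + C1; A2 <- 2 * sxy + C2
  B1 <- mx^2 + my^2 + C1; B2 <- sxx + syy + C2
  S <- (A1 * A2) / (B1 * B2)
  v <- mean(S)
  if (!grad) return(v)
  N <- length(S)
  dF_dmx <- 2 * my * A2 / (B1 * B2) - 2 * mx * A1 * A2 / (B1^2 * B2)
  dF_dsxx <- -A1 * A2 / (B1 * B2^2)
  dF_dsxy <- 2 * A1 / (B1 * B2)
  gmu <- dF_dmx - 2 * mx * dF_dsxx - my * dF_dsxy
  g <- (G(gmu) + 2 * pred * G(dF_dsxx) + target * G(dF_dsxy)) / N
  list(value = v, grad = g)
}

#' Structure loss: the complement of SSIM
#'
#' @inheritParams ssim
#' @return `1 - ssim(pred, target)`, optionally with gradient.
#' @export
structure_loss <- function(pred, target, grad = FALSE, ...) {
  s <- ssim(pred, target, grad = grad, ...)
  if (!grad) return(1 - s)
  list(value = 1 - s$value, grad = -s$grad)
}

#' Fixed feature extractor for the perceptual loss
#'
#' The `seeded_random_conv` backend is a frozen stack of four 3x3
#' convolutions (channels 1-8-16-16-16) with ReLU, He-initialized from the
#' seed; features are tapped after the second and fourth stages. The
#' `pretrained_vgg16` backend is the fidelity option when pretrained weights
#' are available locally; without them it raises an error naming the
#' fallback, so no code path ever downloads anything.
#'
#' @param dims 2 or 3.
#' @param backend "seeded_random_conv" or "pretrained_vgg16".
#' @param seed initialization seed.
#' @return a frozen `feature_extractor`.
#' @export
feature_extractor <- function(dims = 2L, backend = "seeded_random_conv",
                              seed = 42L) {
  backend <- match.arg(backend, c("seeded_random_conv", "pretrained_vgg16"))
  if (backend == "pretrained_vgg16")
    stop("pretrained VGG16 weights are not bundled; ",
         "use backend = \"seeded_random_conv\"")
  chans <- c(1L, 8L, 16L, 16L, 16L)
  layers <- with_seed(seed, lapply(1:4, function(i)
    conv_layer_init(3L, dims, chans[i], chans[i + 1L])))
  structure(list(backend = backend, dims = as.integer(dims), layers = layers,
                 taps = c(2L, 4L), seed = as.integer(seed)),
            class = "feature_extractor")
}

fx_forward <- function(fx, x, keep_cache = FALSE) {
  a <- add_chan(as.array(x))
  caches <- list(); feats <- list()
  for (i in seq_along(fx$layers)) {
    cv <- conv_fw(a, fx$layers[[i]])
    rl <- relu_fw(cv$y)
    caches[[i]] <- list(conv = cv$cache, relu = rl$cache)
    a <- rl$y
    if (i %in% fx$taps) feats[[length(feats) + 1L]] <- a
  }
  list(feats = feats, caches = caches)
}

#' Perceptual loss under a frozen feature extractor
#'
#' Sum over tap points of the mean squared feature difference.
#'
#' @param pred,target equal-shaped arrays.
#' @param fx a [feature_extractor()].
#' @param grad also return the gradient w.r.t. `pred`.
#' @return scalar (>= 0, zero iff all tapped features agree), or
#'   `list(value, grad)`.
#' @export
perceptual_loss <- function(pred, target, fx, grad = FALSE) {
  stopifnot(inherits(fx, "feature_extractor"))
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  fp <- fx_forward(fx, pred, keep_cache = grad)
  ft <- fx_forward(fx, target)
  v <- 0
  dtaps <- vector("list", length(fx$taps))
  for (t in seq_along(fx$taps)) {
    dif <- fp$feats[[t]] - ft$feats[[t]]
    v <- v + mean(dif^2)
    if (grad) dtaps[[t]] <- 2 * dif / length(dif)
  }
  if (!grad) return(v)
  # backprop the tap gradients through the frozen stack (pred branch only)
  d <- array(0, dim(fp$feats[[length(fx$taps)]]))
  for (i in rev(seq_along(fx$layers))) {
    if (i %in% fx$taps) d <- d + dtaps[[match(i, fx$taps)]]
    d <- relu_bw(d, fp$caches[[i]]$relu)
    d <- conv_bw(d, fx$layers[[i]], fp$caches[[i]]$conv)$dx
  }
  list(value = v, grad = drop_chan(d))
}

#' The three composite loss recipes
#'
#' `baseline` = 0.8 MSE + 0.2 TV; `structure` = 1 - SSIM;
#' `visual` = 0.1 MAE + 1.0 TV + 1.0 perceptual.
#'
#' @param name "baseline", "structure" or "visual".
#' @return a `loss_recipe` with named term weights.
#' @export
loss_recipe <- function(name = c("baseline", "structure", "visual")) {
  name <- match.arg(name)
  terms <- switch(name,
    baseline = c(mse = 0.8, tv = 0.2),
    structure = c(ssim_complement = 1.0),
    visual = c(mae = 0.1, tv = 1.0, perceptual = 1.0))
  structure(list(name = name, terms = terms), class = "loss_recipe")
}

#' Weighted composite loss
#'
#' @param recipe a [loss_recipe()] or its name.
#' @param pred,target equal-shaped arrays.
#' @param fx feature extractor, required iff the recipe has a perceptual
#'   term.
#' @param grad also return the gradient w.r.t. `pred`.
#' @return scalar, or `list(value, grad)`.
#' @export
composite_loss <- function(recipe, pred, target, fx = NULL, grad = FALSE) {
  if (is.character(recipe)) recipe <- loss_recipe(recipe)
  stopifnot(inherits(recipe, "loss_recipe"))
  if ("perceptual" %in% names(recipe$terms) && is.null(fx))
    stop("the visual recipe requires a feature extractor (fx)")
  v <- 0; g <- if (grad) array(0, dim(as.array(pred))) else NULL
  for (nm in names(recipe$terms)) {
    w <- recipe$terms[[nm]]
    r <- switch(nm,
      mse = mse_loss(pred, target, grad),
      mae = mae_loss(pred, target, grad),
      tv = tv_loss(pred, grad),
      ssim_complement = structure_loss(pred, target, grad),
      perceptual = perceptual_loss(pred, target, fx, grad))
    if (grad) { v <- v + w * r$value; g <- g + w * r$grad }
    else v <- v + w * r
  }
  if (!grad) return(v)
  list(value = v, grad = g)
}
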