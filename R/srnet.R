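# The residual super-resolution network (2D and 3D variants) and the three
# composite loss recipes. Architecture: 9x9 head convolution, residual
# blocks (two 3x3 convolutions with instance normalization and ReLU, plus an
# additive skip), two x2 resize-convolution stages (nearest-neighbour resize
# followed by a 3x3 convolution, avoiding transposed-convolution
# checkerboard), and a linear 9x9 tail; total upscale factor 4. Reflect
# padding everywhere, so constants propagate exactly.

#' Network configuration
#'
#' @param dims 2 or 3.
#' @param n_residual_blocks number of residual blocks (default 4).
#' @param base_channels feature width (default 64).
#' @param global_skip add a parameter-free global residual connection: the
#'   output is the network's prediction plus a linear x4 upsampling of the
#'   input. The untrained network then starts at interpolation quality and
#'   training learns the residual detail, which converges far faster under
#'   short schedules. TRUE by default.
#' @param seed initialization seed; equal seeds give identical parameters.
#' @return an `sr_network_config`. The upscale factor is fixed at 4,
#'   realized as two x2 resize-convolution stages.
#' @export
sr_network_config <- function(dims = 2L, n_residual_blocks = 4L,
                              base_channels = 64L, global_skip = TRUE,
                              seed = 1L) {
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  if (n_residual_blocks < 1L) stop("need at least one residual block")
  structure(list(dims = as.integer(dims),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 base_channels = as.integer(base_channels), upscale = 4L,
                 upsample_mode = "resize_convolution",
                 global_skip = isTRUE(global_skip),
                 seed = as.integer(seed)),
            class = "sr_network_config")
}

#' Build an (untrained) super-resolution network
#'
#' @param config an [sr_network_config()].
#' @return a `bsr_model` with seeded He-initialized parameters; maps an
#'   n^dims input to a (4n)^dims output for any n >= 4.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "sr_network_config"))
  nd <- config$dims; C <- config$base_channels
  params <- with_seed(config$seed, {
    p <- list(head = conv_layer_init(9L, nd, 1L, C),
              head_in = inorm_layer_init(C))
    p$blocks <- lapply(seq_len(config$n_residual_blocks), function(i)
      list(conv1 = conv_layer_init(3L, nd, C, C), in1 = inorm_layer_init(C),
           conv2 = conv_layer_init(3L, nd, C, C), in2 = inorm_layer_init(C)))
    p$up <- lapply(1:2, function(i)
      list(conv = conv_layer_init(3L, nd, C, C), inorm = inorm_layer_init(C)))
    p$tail <- conv_layer_init(9L, nd, C, 1L)
    # damp the tail so the initial output is dominated by the global skip
    # (when enabled) rather than by random residual noise
    p$tail$W <- p$tail$W * 0.05
    p
  })
  structure(list(config = config, params = params), class = "bsr_model")
}

#' @export
print.bsr_model <- function(x, ...) {
  np <- sum(vapply(param_leaves(x$params), function(p)
    length(get_path(x$params, p)), numeric(1)))
  cat(sprintf("<bsr_model> %dD, %d residual blocks, %d channels, %s parameters\n",
              x$config$dims, x$config$n_residual_blocks,
              x$config$base_channels, format(np, big.mark = ",")))
  invisible(x)
}

add_chan <- function(x) array(x, c(dim(x), 1L))
drop_chan <- function(x) array(x, head(dim(x), -1L))

# Forward pass; returns the output (no channel axis) and, if keep_cache,
# everything needed for the backward pass.
net_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  caches <- list()
  a <- add_chan(as.array(x))
  kc <- keep_cache
  cv <- conv_fw(a, p$head, kc); caches$head <- cv$cache
  io <- inorm_fw(cv$y, p$head_in); caches$head_in <- io$cache
  rl <- relu_fw(io$y); caches$head_relu <- rl$cache
  h <- rl$y
  caches$blocks <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    bl <- p$blocks[[i]]
    c1 <- conv_fw(h, bl$conv1, kc); i1 <- inorm_fw(c1$y, bl$in1)
    r1 <- relu_fw(i1$y)
    c2 <- conv_fw(r1$y, bl$conv2, kc); i2 <- inorm_fw(c2$y, bl$in2)
    caches$blocks[[i]] <- list(c1 = c1$cache, i1 = i1$cache, r1 = r1$cache,
                               c2 = c2$cache, i2 = i2$cache)
    h <- h + i2$y
  }
  caches$up <- vector("list", 2L)
  for (u in 1:2) {
    us <- upnn2_fw(h)
    cu <- conv_fw(us$y, p$up[[u]]$conv, kc)
    iu <- inorm_fw(cu$y, p$up[[u]]$inorm)
    ru <- relu_fw(iu$y)
    caches$up[[u]] <- list(us = us$cache, cu = cu$cache, iu = iu$cache,
                           ru = ru$cache)
    h <- ru$y
  }
  tl <- conv_fw(h, p$tail, kc); caches$tail <- tl$cache
  out <- drop_chan(tl$y)
  if (isTRUE(model$config$global_skip)) {
    xs <- as.array(x)
    out <- out + resample_array(xs, 4L * dim(xs), method = "linear",
                                antialias = FALSE)
  }
  if (keep_cache) list(out = out, caches = caches) else list(out = out)
}

# Backward pass: dout has the output's shape; returns parameter gradients
# mirroring the parameter tree.
net_backward <- function(model, caches, dout) {
  p <- model$params
  g <- list()
  d <- add_chan(as.array(dout))
  tb <- conv_bw(d, p$tail, caches$tail)
  g$tail <- list(W = tb$dW, b = tb$db)
  d <- tb$dx
  g$up <- vector("list", 2L)
  for (u in 2:1) {
    cc <- caches$up[[u]]
    d <- relu_bw(d, cc$ru)
    ib <- inorm_bw(d, p$up[[u]]$inorm, cc$iu)
    cb <- conv_bw(ib$dx, p$up[[u]]$conv, cc$cu)
    g$up[[u]] <- list(conv = list(W = cb$dW, b = cb$db),
                      inorm = list(gamma = ib$dgamma, beta = ib$dbeta))
    d <- upnn2_bw(cb$dx, cc$us)
  }
  g$blocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    bl <- p$blocks[[i]]; cc <- caches$blocks[[i]]
    # d flows both through the block and the skip
    i2b <- inorm_bw(d, bl$in2, cc$i2)
    c2b <- conv_bw(i2b$dx, bl$conv2, cc$c2)
    dr <- relu_bw(c2b$dx, cc$r1)
    i1b <- inorm_bw(dr, bl$in1, cc$i1)
    c1b <- conv_bw(i1b$dx, bl$conv1, cc$c1)
    g$blocks[[i]] <- list(
      conv1 = list(W = c1b$dW, b = c1b$db),
      in1 = list(gamma = i1b$dgamma, beta = i1b$dbeta),
      conv2 = list(W = c2b$dW, b = c2b$db),
      in2 = list(gamma = i2b$dgamma, beta = i2b$dbeta))
    d <- d + c1b$dx
  }
  d <- relu_bw(d, caches$head_relu)
  ib <- inorm_bw(d, p$head_in, caches$head_in)
  cb <- conv_bw(ib$dx, p$head, caches$head)
  g$head <- list(W = cb$dW, b = cb$db)
  g$head_in <- list(gamma = ib$dgamma, beta = ib$dbeta)
  g
}

#' Predict the super-resolved tile for a low-resolution tile
#'
#' Generic so that stub models (constant, perfect-oracle, arbitrary function)
#' can stand in for a trained network in inference tests.
#'
#' @param model a model object.
#' @param tile low-resolution tile (matrix or 3D array).
#' @param info list with tile provenance (`origin`, `slice`, `plane`),
#'   ignored by real networks.
#' @return the x4 upscaled tile, clamped to `[0, 1]`.
#' @export
predict_tile <- function(model, tile, info = list()) UseMethod("predict_tile")

#' @export
predict_tile.bsr_model <- function(model, tile, info = list()) {
  nd <- length(dim(as.array(tile)))
  if (nd != model$config$dims)
    stop("model dims (", model$config$dims, ") do not match tile dims (", nd, ")")
  clip01(net_forward(model, tile)$out)
}

#' Stub models for inference testing
#'
#' `constant_stub(value)` predicts a constant tile; `oracle_stub(hr_volume)`
#' returns the true high-resolution window co-located with the input tile;
#' `function_stub(fn)` applies `fn(tile)`.
#'
#' @param value,hr,fn stub payloads.
#' @return model objects usable with [predict_tile()] and the sliding-window
#'   inference functions.
#' @export
constant_stub <- function(value = 0.5)
  structure(list(value = value), class = c("constant_stub", "stub_model"))

#' @rdname constant_stub
#' @export
oracle_stub <- function(hr)
  structure(list(hr = as_volume_data(hr)),
            class = c("oracle_stub", "stub_model"))

#' @rdname constant_stub
#' @export
function_stub <- function(fn)
  structure(list(fn = fn), class = c("function_stub", "stub_model"))

#' @export
predict_tile.constant_stub <- function(model, tile, info = list()) {
  array(model$value, 4L * dim(as.array(tile)))
}

#' @export
predict_tile.function_stub <- function(model, tile, info = list()) {
  model$fn(tile)
}

#' @export
predict_tile.oracle_stub <- function(model, tile, info = list()) {
  d <- dim(as.array(tile))
  o <- info$origin %||% rep(1L, length(d))
  ho <- 4L * (o - 1L) + 1L
  hr <- model$hr
  if (length(d) == 2L) {
    pl <- info$plane %||% 1L
    s <- info$slice %||% 1L
    sl <- switch(pl, hr[s, , ], hr[, s, ], hr[, , s])
    sl[ho[1]:(ho[1] + 4L * d[1] - 1L), ho[2]:(ho[2] + 4L * d[2] - 1L)]
  } else {
    hr[ho[1]:(ho[1] + 4L * d[1] - 1L), ho[2]:(ho[2] + 4L * d[2] - 1L),
       ho[3]:(ho[3] + 4L * d[3] - 1L)]
  }
}
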