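# Training: Adam optimization of an SR network on patch pairs under a loss
# recipe, with patient-grouped cross-validation and per-fold metric reports.

#' Training configuration
#'
#' The published learning rate is 1e-4; the exponential-decay parameters use
#' the standard Adam values (0.9, 0.999) with optional decoupled weight
#' decay.
#'
#' @param recipe loss recipe name ("baseline", "structure", "visual").
#' @param epochs number of epochs (>= 1).
#' @param learning_rate Adam step size.
#' @param betas Adam exponential-decay pair.
#' @param weight_decay optional L2 coefficient (0 disables).
#' @param batch_size minibatch size.
#' @param folds number of cross-validation folds.
#' @param seeds integer seeds; [cross_validate()] trains each fold once per
#'   seed.
#' @param crop_lr network input side; larger patches are randomly cropped to
#'   this each epoch (target window x4).
#' @param augment optional [augment_policy()] applied to training patches.
#' @return a `train_config`.
#' @export
train_config <- function(recipe = "structure", epochs = 50L,
                         learning_rate = 1e-4, betas = c(0.9, 0.999),
                         weight_decay = 0, batch_size = 32L, folds = 4L,
                         seeds = 1L, crop_lr = 16L, augment = NULL) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(recipe = recipe, epochs = as.integer(epochs),
                 learning_rate = learning_rate, betas = betas,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 folds = as.integer(folds), seeds = as.integer(seeds),
                 crop_lr = as.integer(crop_lr), augment = augment),
            class = "train_config")
}

adam_init <- function(params) {
  leaves <- param_leaves(params)
  list(m = lapply(leaves, function(p) get_path(params, p) * 0),
       v = lapply(leaves, function(p) get_path(params, p) * 0),
       t = 0L, leaves = leaves)
}

adam_step <- function(params, grads, state, lr, betas, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (i in seq_along(state$leaves)) {
    p <- state$leaves[[i]]
    g <- get_path(grads, p)
    if (weight_decay > 0) g <- g + weight_decay * get_path(params, p)
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g^2
    upd <- lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    params <- set_path(params, p, get_path(params, p) - upd)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(acc, g, leaves) {
  if (is.null(acc)) return(g)
  for (p in leaves) acc <- set_path(acc, p, get_path(acc, p) + get_path(g, p))
  acc
}

scale_grads <- function(g, leaves, s) {
  for (p in leaves) g <- set_path(g, p, get_path(g, p) * s)
  g
}

# Evaluate a model on validation pairs: recipe loss plus MSE/PSNR/SSIM on
# the clamped predictions (inference convention).
eval_pairs <- function(model, pairs, recipe, fx, crop_lr) {
  losses <- mses <- ssims <- numeric(length(pairs))
  ssim_only <- identical(recipe$name, "structure")
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    if (any(dim(pr$lr) != crop_lr))
      pr <- crop_pad_to_net(pr, crop_lr, origin = rep(1L, length(dim(pr$lr))))
    pred <- clip01(net_forward(model, pr$lr)$out)
    mses[i] <- mse_loss(pred, pr$hr)
    ssims[i] <- ssim(pred, pr$hr)
    # the structure recipe is 1 - SSIM, already computed above
    losses[i] <- if (ssim_only) 1 - ssims[i]
                 else composite_loss(recipe, pred, pr$hr, fx = fx)
  }
  m <- mean(mses)
  list(loss = mean(losses), mse = m, psnr = psnr_from_mse(m),
       ssim = mean(ssims))
}

#' Train one cross-validation fold
#'
#' Deterministic given the seed: data order, cropping and augmentation all
#' draw from a seeded stream. The report records the per-epoch mean training
#' loss (the loss at epoch e+1 is computed with the parameters updated
#' during epoch e) and validation MSE/PSNR/SSIM before and after training.
#'
#' @param pairs list of `patch_pair` objects.
#' @param split `list(train, val)` index vectors (from [grouped_kfold()]).
#' @param net_config an [sr_network_config()].
#' @param config a [train_config()].
#' @param seed training seed (overrides `config$seeds[1]`).
#' @param fold_id identifier stored in the report.
#' @return `list(model, report)`; the report is a `fold_report` with fields
#'   `fold_id`, `seed`, `train_loss` (per epoch), `val0` and `val`
#'   (metric lists before/after training).
#' @export
train_fold <- function(pairs, split, net_config, config, seed = NULL,
                       fold_id = 1L) {
  stopifnot(inherits(config, "train_config"))
  if (!length(split$train) || !length(split$val)) stop("empty fold")
  seed <- seed %||% config$seeds[1]
  # leakage guard: asserted on every run
  ptr <- unique(vapply(pairs[split$train], `[[`, character(1), "patient_id"))
  pva <- unique(vapply(pairs[split$val], `[[`, character(1), "patient_id"))
  if (length(intersect(ptr, pva)))
    stop("patient leakage between train and validation sets")
  recipe <- loss_recipe(config$recipe)
  nd <- length(dim(pairs[[1]]$lr))
  fx <- if ("perceptual" %in% names(recipe$terms))
    feature_extractor(dims = nd) else NULL
  net_config$dims <- nd
  model <- build_network(
    sr_network_config(nd, net_config$n_residual_blocks,
                      net_config$base_channels,
                      global_skip = net_config$global_skip %||% TRUE,
                      seed = derive_seed(seed, "init")))
  st <- adam_init(model$params)
  train_losses <- numeric(config$epochs)
  val0 <- eval_pairs(model, pairs[split$val], recipe, fx, config$crop_lr)
  with_seed(derive_seed(seed, "order"), {
    for (ep in seq_len(config$epochs)) {
      idx <- sample(split$train)
      nb <- ceiling(length(idx) / config$batch_size)
      ep_loss <- 0; nseen <- 0
      for (b in seq_len(nb)) {
        bidx <- idx[((b - 1L) * config$batch_size + 1L):
                      min(b * config$batch_size, length(idx))]
        gacc <- NULL
        bloss <- 0
        for (i in bidx) {
          pr <- pairs[[i]]
          if (!is.null(config$augment)) pr <- augment_pair(pr, config$augment)
          if (any(dim(pr$lr) != config$crop_lr))
            pr <- crop_pad_to_net(pr, config$crop_lr)
          fwd <- net_forward(model, pr$lr, keep_cache = TRUE)
          cl <- composite_loss(recipe, fwd$out, pr$hr, fx = fx, grad = TRUE)
          if (!is.finite(cl$value))
            stop("non-finite loss at epoch ", ep, " (NaN guard)")
          g <- net_backward(model, fwd$caches, cl$grad)
          gacc <- accumulate_grads(gacc, g, st$leaves)
          bloss <- bloss + cl$value
        }
        gacc <- scale_grads(gacc, st$leaves, 1 / length(bidx))
        upd <- adam_step(model$params, gacc, st, config$learning_rate,
                         config$betas, weight_decay = config$weight_decay)
        model$params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + bloss; nseen <- nseen + length(bidx)
      }
      train_losses[ep] <- ep_loss / nseen
    }
  })
  val <- eval_pairs(model, pairs[split$val], recipe, fx, config$crop_lr)
  report <- structure(list(fold_id = fold_id, seed = seed,
                           train_loss = train_losses, val0 = val0, val = val),
                      class = "fold_report")
  list(model = model, report = report)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in decibels. Identical inputs have infinite
#' PSNR; that case is encoded as the documented cap of 120 dB
#' (`MSE <= 1e-12` at unit peak).
#'
#' @param pred,target equal-shaped arrays.
#' @param peak dynamic range (1 for float01 volumes).
#' @return PSNR in dB.
#' @export
psnr <- function(pred, target, peak = 1.0) {
  psnr_from_mse(mse_loss(pred, target), peak)
}

psnr_from_mse <- function(mse, peak = 1.0) {
  10 * log10(peak^2 / max(mse, 1e-12))
}

#' Patient-grouped cross-validation with a summary over folds and seeds
#'
#' @param pairs list of `patch_pair` objects.
#' @param net_config an [sr_network_config()].
#' @param config a [train_config()]; `config$folds` folds are trained for
#'   every seed in `config$seeds`.
#' @param kfold_seed seed for the patient split.
#' @return list with `reports` (length folds x seeds), `models` (one per
#'   report) and `summary`, a data.frame of mean and standard error
#'   (sd/sqrt(n) over reports) for validation MSE, PSNR and SSIM.
#' @export
cross_validate <- function(pairs, net_config, config, kfold_seed = 1L) {
  splits <- grouped_kfold(pairs, config$folds, kfold_seed)
  reports <- list(); models <- list()
  for (s in config$seeds) for (f in seq_along(splits)) {
    r <- train_fold(pairs, splits[[f]], net_config, config, seed = s,
                    fold_id = f)
    reports[[length(reports) + 1L]] <- r$report
    models[[length(models) + 1L]] <- r$model
  }
  metric <- function(nm) vapply(reports, function(r) r$val[[nm]], numeric(1))
  sem <- function(x) sd(x) / sqrt(length(x))
  summary <- data.frame(
    metric = c("mse", "psnr", "ssim"),
    mean = c(mean(metric("mse")), mean(metric("psnr")), mean(metric("ssim"))),
    sem = c(sem(metric("mse")), sem(metric("psnr")), sem(metric("ssim"))))
  list(reports = reports, models = models, summary = summary)
}
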