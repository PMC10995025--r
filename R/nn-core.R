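# Minimal convolutional-network engine. Activations are (H, W, C) or
# (D, H, W, C) arrays; convolutions are stride-1 with symmetric-reflect
# borders, evaluated as im2col gathers followed by one BLAS matrix product.
# Every layer has an explicit backward pass; gradients are checked against
# finite differences in the test suite.

.bsr_idx_cache <- new.env(parent = emptyenv())

# Gather-index matrix (k^nd * C rows, length(positions) cols) mapping each
# output position's receptive field into the flattened input array, with
# reflected out-of-range coordinates. Row order matches the weight layout:
# column-major over (kernel axes..., input channel). Full-grid indices are
# cached; position subsets (used by the chunked forward) are not.
conv_index <- function(sp_dim, k, C, positions = NULL) {
  full <- is.null(positions)
  key <- paste(c(sp_dim, k, C), collapse = "_")
  if (full) {
    hit <- .bsr_idx_cache[[key]]
    if (!is.null(hit)) return(hit)
    positions <- seq_len(prod(sp_dim))
  }
  nd <- length(sp_dim)
  r <- (k - 1L) %/% 2L
  N <- length(positions)
  coords <- arrayInd(positions, sp_dim)  # N x nd
  offs <- as.matrix(expand.grid(rep(list((-r):r), nd)))  # k^nd x nd, axis1 fastest
  nk <- nrow(offs)
  idx_sp <- matrix(0L, nk, N)
  strides <- cumprod(c(1L, sp_dim[-nd]))
  for (t in seq_len(nk)) {
    lin <- 1L
    linv <- rep(0L, N)
    for (a in seq_len(nd)) {
      ca <- reflect_index(coords[, a] + offs[t, a], sp_dim[a])
      linv <- linv + (ca - 1L) * strides[a]
    }
    idx_sp[t, ] <- linv + 1L
  }
  voxN <- prod(sp_dim)
  idx <- matrix(0L, nk * C, N)
  for (c in seq_len(C))
    idx[((c - 1L) * nk + 1L):(c * nk), ] <- idx_sp + (c - 1L) * voxN
  if (full) .bsr_idx_cache[[key]] <- idx
  idx
}

# Transposed full-grid gather index (N x nk), cached; used by the backward
# scatter so no large transpose happens per call.
conv_index_t <- function(sp_dim, k, C) {
  key <- paste(c(sp_dim, k, C, "t"), collapse = "_")
  hit <- .bsr_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  idxT <- t(conv_index(sp_dim, k, C))
  .bsr_idx_cache[[key]] <- idxT
  idxT
}

# Entries above which the forward pass streams position chunks instead of
# materializing one full im2col matrix (memory guard for large 3D tiles).
.BSR_COL_LIMIT <- 2^24

# layer: list(W = Cout x (k^nd * Cin) matrix, b = length Cout, k = kernel)
conv_fw <- function(x, layer, keep_cache = TRUE) {
  d <- dim(x)
  nd <- length(d) - 1L
  sp <- d[seq_len(nd)]
  cin <- d[nd + 1L]
  N <- prod(sp)
  nk <- layer$k^nd * cin
  if (!keep_cache && nk * N > .BSR_COL_LIMIT) {
    cout <- nrow(layer$W)
    out <- matrix(0, cout, N)
    step <- max(1L, as.integer(.BSR_COL_LIMIT %/% nk))
    for (s in seq(1L, N, by = step)) {
      cols <- s:min(s + step - 1L, N)
      idx <- conv_index(sp, layer$k, cin, positions = cols)
      out[, cols] <- layer$W %*% matrix(x[idx], nk) + layer$b
    }
    return(list(y = array(t(out), c(sp, cout)), cache = NULL))
  }
  idx <- conv_index(sp, layer$k, cin)
  col <- x[idx]
  dim(col) <- dim(idx)
  outT <- crossprod(col, t(layer$W))  # N x Cout, no large transpose
  if (any(layer$b != 0)) outT <- outT + rep(layer$b, each = N)
  y <- outT
  dim(y) <- c(sp, nrow(layer$W))
  list(y = y, cache = if (keep_cache)
    list(col = col, sp = sp, cin = cin, k = layer$k) else NULL)
}

conv_bw <- function(dout, layer, cache) {
  Cout <- nrow(layer$W)
  N <- prod(cache$sp)
  A <- dout
  dim(A) <- c(N, Cout)
  dW <- t(cache$col %*% A)                       # Cout x (k^nd*Cin)
  db <- colSums(A)
  dcolT <- A %*% layer$W                         # N x (k^nd*Cin)
  idxT <- conv_index_t(cache$sp, cache$k, cache$cin)
  dx <- cpp_scatter_add(dcolT, idxT, as.integer(N * cache$cin))
  list(dx = array(dx, c(cache$sp, cache$cin)), dW = dW, db = db)
}

# Instance normalization (biased variance, eps 1e-5), per-channel affine.
inorm_fw <- function(x, layer, eps = 1e-5) {
  d <- dim(x)
  C <- d[length(d)]
  N <- prod(d) / C
  xm <- matrix(x, N, C)
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = N)) * rep(istd, each = N)
  y <- xhat * rep(layer$gamma, each = N) + rep(layer$beta, each = N)
  list(y = array(y, d), cache = list(xhat = xhat, istd = istd, N = N, d = d))
}

inorm_bw <- function(dout, layer, cache) {
  N <- cache$N; d <- cache$d; C <- d[length(d)]
  dm <- matrix(dout, N, C)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * rep(layer$gamma, each = N)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- rep(cache$istd, each = N) *
    (dxhat - rep(m1, each = N) - cache$xhat * rep(m2, each = N))
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bw <- function(dout, cache) dout * cache

# Nearest-neighbour x2 upsampling on all spatial axes (channel axis last).
upnn2_fw <- function(x) {
  d <- dim(x)
  nd <- length(d) - 1L
  if (nd == 2L) y <- x[rep(seq_len(d[1]), each = 2L),
                       rep(seq_len(d[2]), each = 2L), , drop = FALSE]
  else y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L),
              rep(seq_len(d[3]), each = 2L), , drop = FALSE]
  list(y = y, cache = d)
}

upnn2_bw <- function(dout, cache) {
  d <- cache
  nd <- length(d) - 1L
  if (nd == 2L) {
    o1 <- seq(1L, 2L * d[1], by = 2L); o2 <- seq(1L, 2L * d[2], by = 2L)
    dout[o1, o2, , drop = FALSE] + dout[o1 + 1L, o2, , drop = FALSE] +
      dout[o1, o2 + 1L, , drop = FALSE] + dout[o1 + 1L, o2 + 1L, , drop = FALSE]
  } else {
    o1 <- seq(1L, 2L * d[1], by = 2L); o2 <- seq(1L, 2L * d[2], by = 2L)
    o3 <- seq(1L, 2L * d[3], by = 2L)
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      acc <- acc + dout[o1 + a, o2 + b, o3 + cc, , drop = FALSE]
    acc
  }
}

conv_layer_init <- function(k, nd, cin, cout) {
  fanin <- k^nd * cin
  list(W = matrix(rnorm(cout * fanin, sd = sqrt(2 / fanin)), cout, fanin),
       b = numeric(cout), k = as.integer(k))
}

inorm_layer_init <- function(C) list(gamma = rep(1, C), beta = numeric(C))

# Flatten/unflatten a nested parameter list for the optimizer. Paths are
# lists of names/indices so unnamed list levels (the block/up stacks) work.
param_leaves <- function(params, path = list()) {
  if (is.list(params) && !is.null(params$W)) {
    return(list(c(path, "W"), c(path, "b")))
  }
  if (is.list(params) && !is.null(params$gamma)) {
    return(list(c(path, "gamma"), c(path, "beta")))
  }
  out <- list()
  keys <- names(params)
  for (i in seq_along(params)) {
    key <- if (!is.null(keys) && nzchar(keys[i])) keys[i] else i
    out <- c(out, param_leaves(params[[i]], c(path, key)))
  }
  out
}

get_path <- function(x, path) { for (p in path) x <- x[[p]]; x }
set_path <- function(x, path, value) {
  if (length(path) == 1L) { x[[path[[1]]]] <- value; return(x) }
  x[[path[[1]]]] <- set_path(x[[path[[1]]]], path[-1], value)
  x
}
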