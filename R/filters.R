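# Separable spatial filtering and resampling on plain numeric arrays.
# All operators use symmetric (reflect) borders unless noted; the median
# filter (compiled) replicates edges. These are the shared primitives behind
# the degradation cascade, the synthetic generators and the benchmarks.

#' Sampled 1D Gaussian kernel
#'
#' @param sigma standard deviation in samples; `sigma = 0` gives the identity.
#' @param size odd kernel length; default covers +/- 3 sigma.
#' @return numeric vector summing to 1.
#' @keywords internal
gaussian_kernel1d <- function(sigma, size = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  if (size %% 2L == 0L) stop("Gaussian kernel size must be odd")
  r <- (size - 1L) / 2L
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Correlate a 2D/3D array with a 1D kernel along one axis, reflect borders.
filter_axis <- function(x, kernel, axis) {
  d <- dim(x)
  if (length(kernel) == 1L) return(x * kernel)
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  n <- d[axis]
  for (j in seq_along(kernel)) {
    off <- j - 1L - r
    idx <- reflect_index(seq_len(n) + off, n)
    shifted <- switch(length(d),
      NULL,
      if (axis == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE],
      switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
             x[, , idx, drop = FALSE]))
    out <- out + kernel[j] * shifted
  }
  out
}

#' Separable Gaussian blur of a 2D or 3D array
#'
#' @param x numeric array.
#' @param sigma scalar or per-axis standard deviations (in voxels).
#' @param size odd kernel size; default +/- 3 sigma per axis.
#' @param axes axes to filter (default all).
#' @return filtered array, same shape.
#' @export
gaussian_blur <- function(x, sigma, size = NULL, axes = seq_along(dim(x))) {
  d <- dim(x)
  sigma <- rep(sigma, length.out = length(d))
  for (a in axes) {
    if (sigma[a] > 0) x <- filter_axis(x, gaussian_kernel1d(sigma[a], size), a)
  }
  x
}

#' Median filter of a 2D or 3D array
#'
#' Cubic (square) neighbourhood of odd side `size`, replicate borders.
#'
#' @param x numeric array (2D or 3D).
#' @param size odd window side, default 3.
#' @return filtered array.
#' @export
median_filter <- function(x, size = 3L) {
  if (size %% 2L == 0L) stop("median filter size must be odd")
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% 2:3)) stop("x must be a 2D or 3D array")
  cpp_median_filter(as.numeric(x), as.integer(d), as.integer((size - 1L) / 2L))
}

# Resampling weight matrix (n_out x n_in) for one axis.
# Output sample i (1-based) is taken at input coordinate
# (i - 0.5) * n_in / n_out + 0.5 (grid-centre alignment).
# method "linear" uses a triangle kernel, "cubic" a Catmull-Rom kernel
# (a = -1/2); when downscaling with antialias = TRUE the kernel is widened by
# the scale factor. Reflect borders.
.bsr_rw_cache <- new.env(parent = emptyenv())

resample_weights <- function(n_in, n_out, method = c("linear", "cubic"),
                             antialias = TRUE) {
  method <- match.arg(method)
  key <- paste(n_in, n_out, method, antialias, sep = "_")
  hit <- .bsr_rw_cache[[key]]
  if (!is.null(hit)) return(hit)
  scale <- n_in / n_out
  width <- if (antialias && scale > 1) scale else 1
  support <- if (method == "linear") 1 else 2
  kern <- function(u) {
    if (method == "linear") pmax(0, 1 - abs(u))
    else {
      a <- -0.5; au <- abs(u)
      ifelse(au < 1, (a + 2) * au^3 - (a + 3) * au^2 + 1,
             ifelse(au < 2, a * au^3 - 5 * a * au^2 + 8 * a * au - 4 * a, 0))
    }
  }
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    c_in <- (i - 0.5) * scale + 0.5
    rad <- support * width
    jr <- floor(c_in - rad):ceiling(c_in + rad)
    w <- kern((jr - c_in) / width)
    keep <- w != 0
    jr <- jr[keep]; w <- w[keep]
    if (sum(w) == 0) { jr <- round(c_in); w <- 1 }
    w <- w / sum(w)
    jj <- reflect_index(jr, n_in)
    for (t in seq_along(jj)) W[i, jj[t]] <- W[i, jj[t]] + w[t]
  }
  .bsr_rw_cache[[key]] <- W
  W
}

# Apply an n_out x n_in weight matrix along one axis of a 2D/3D array.
apply_axis_matrix <- function(x, W, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[axis])
  y <- W %*% m
  d2 <- d[perm]; d2[1] <- nrow(W)
  yp <- array(y, d2)
  aperm(yp, order(perm))
}

#' Separable resampling of an array to new extents
#'
#' @param x 2D or 3D numeric array.
#' @param new_dim target extents (same length as `dim(x)`).
#' @param method "linear" or "cubic" (Catmull-Rom).
#' @param antialias widen the kernel when downscaling.
#' @return resampled array.
#' @export
resample_array <- function(x, new_dim, method = c("linear", "cubic"),
                           antialias = TRUE) {
  method <- match.arg(method)
  d <- dim(x)
  stopifnot(length(new_dim) == length(d))
  for (a in seq_along(d)) {
    if (new_dim[a] != dim(x)[a]) {
      W <- resample_weights(dim(x)[a], new_dim[a], method, antialias)
      x <- apply_axis_matrix(x, W, a)
    }
  }
  x
}

#' Block-average downscaling by an integer factor
#'
#' Trailing voxels that do not fill a complete block are dropped, so output
#' extents are `floor(n / factor)` on the averaged axes.
#'
#' @param x 2D or 3D array.
#' @param factor integer downscale factor.
#' @param axes axes to average (default all).
#' @return downscaled array.
#' @export
block_average <- function(x, factor = 4L, axes = seq_along(dim(x))) {
  d <- dim(x)
  for (a in axes) {
    n <- dim(x)[a]
    nb <- n %/% factor
    if (nb < 1L) stop("extent too small for block averaging")
    idx <- seq_len(nb * factor)
    x <- switch(length(d),
      NULL,
      if (a == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE],
      switch(a, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
             x[, , idx, drop = FALSE]))
    # average groups of `factor` along axis a via a sparse-free matrix product
    W <- matrix(0, nb, nb * factor)
    W[cbind(rep(seq_len(nb), each = factor), seq_len(nb * factor))] <- 1 / factor
    x <- apply_axis_matrix(x, W, a)
  }
  x
}

clip01 <- function(x) pmin(pmax(x, 0), 1)  # x first: pmin/pmax keep its dim
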