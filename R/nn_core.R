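# Neural-network primitives: valid cross-correlation, average pooling,
# sigmoid, dense layers and softmax/cross-entropy, each with an exact
# backward pass.  Feature maps are arrays with dim (height, width, channels)
# and batches append a trailing sample dimension: (h, w, c, n).  Kernels use
# dim (k, k, in_channels, out_channels).  Everything is vectorized through an
# im2col/col2im pair so training stays fast in pure R.

#' Convolution layer parameters
#'
#' @param kernels 4-D array, dim `(k, k, in_channels, out_channels)`.
#' @param biases numeric vector, one per output channel.
#' @param stride positive integer stride (both axes).
#' @return An object of class `conv_layer_params`.
#' @export
conv_layer_params <- function(kernels, biases, stride = 1L) {
  stopifnot(is.array(kernels), length(dim(kernels)) == 4L)
  k <- dim(kernels)
  if (k[1] != k[2]) stop("kernels must be square")
  if (k[1] < 1L) stop("kernel size must be >= 1")
  if (length(biases) != k[4]) stop("one bias per output channel required")
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  structure(list(kernels = kernels, biases = as.numeric(biases),
                 stride = stride),
            class = "conv_layer_params")
}

#' Dense (fully connected) layer parameters
#'
#' @param weights matrix, dim `(out_dim, in_dim)`.
#' @param biases numeric vector of length `out_dim`.
#' @return An object of class `dense_layer_params`.
#' @export
dense_layer_params <- function(weights, biases) {
  stopifnot(is.matrix(weights))
  if (length(biases) != nrow(weights))
    stop("bias length must equal the number of output units")
  structure(list(weights = weights, biases = as.numeric(biases)),
            class = "dense_layer_params")
}

# Coerce a single map (h,w) or stack (h,w,c) to a batch array (h,w,c,n).
as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix or array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("input must have 2, 3 or 4 dimensions")
  x
}

# Patch-extraction index matrix for im2col.
# Rows: k*k*in_ch patch elements (row-fastest, then col, then channel);
# columns: output positions (row-fastest) for every image in the batch.
conv_index <- function(h, w, cin, k, stride, n) {
  ti <- seq.int(1L, h - k + 1L, by = stride)
  tj <- seq.int(1L, w - k + 1L, by = stride)
  off <- as.vector(outer(rep(seq_len(k), times = k) - 1L +
                           (rep(seq_len(k), each = k) - 1L) * h,
                         (seq_len(cin) - 1L) * h * w, "+"))
  corners <- as.vector(outer(ti, (tj - 1L) * h, "+"))
  idx1 <- outer(off, corners, "+")                    # one image
  if (n == 1L) return(list(idx = idx1, oh = length(ti), ow = length(tj)))
  plane <- h * w * cin
  idx <- idx1[, rep(seq_len(ncol(idx1)), times = n)] +
    rep((seq_len(n) - 1L) * plane, each = nrow(idx1) * ncol(idx1))
  dim(idx) <- c(nrow(idx1), ncol(idx1) * n)
  list(idx = idx, oh = length(ti), ow = length(tj))
}

#' 2-D valid convolution (cross-correlation) forward pass
#'
#' Implements the modern CNN convention: cross-correlation without kernel
#' flip, no padding.  Output spatial size is
#' `floor((in - k)/stride) + 1` per axis.
#'
#' @param input array `(h, w, c)` or batch `(h, w, c, n)`; a plain matrix is
#'   treated as a single one-channel map.
#' @param params a [conv_layer_params()] object.
#' @param keep_cache keep forward state needed by [conv2d_backward()].
#' @return The output feature-map array `(oh, ow, out_channels[, n])`, with a
#'   `"cache"` attribute when `keep_cache = TRUE`.
#' @export
conv2d_valid <- function(input, params, keep_cache = FALSE) {
  single <- length(dim(input) %||% dim(as.matrix(input))) < 4L
  x <- as_batch(input)
  d <- dim(x)
  kd <- dim(params$kernels)
  k <- kd[1]
  if (d[3] != kd[3]) stop("input channels do not match kernel channels")
  if (d[1] < k || d[2] < k) stop("kernel larger than input")
  ci <- conv_index(d[1], d[2], d[3], k, params$stride, d[4])
  # index the flattened vector: a matrix subscript with ncol == length(dim)
  # would otherwise be read as coordinate rows
  P <- matrix(as.vector(x)[ci$idx], nrow = nrow(ci$idx))
  W <- matrix(params$kernels, ncol = kd[4])            # (k*k*cin) x cout
  out <- crossprod(W, P) + params$biases               # cout x (oh*ow*n)
  out <- aperm(array(out, c(kd[4], ci$oh, ci$ow, d[4])), c(2, 3, 1, 4))
  if (single && d[4] == 1L) dim(out) <- dim(out)[1:3]
  if (keep_cache)
    attr(out, "cache") <- list(idx = ci$idx, P = P, in_dim = d,
                               oh = ci$oh, ow = ci$ow)
  out
}

#' Backward pass of [conv2d_valid()]
#'
#' @param d_out gradient of the loss w.r.t. the layer output, same shape as
#'   the forward output.
#' @param params the layer parameters used in the forward pass.
#' @param cache the `"cache"` attribute from `conv2d_valid(..., keep_cache = TRUE)`.
#' @return list with `d_kernels`, `d_biases`, `d_input`.
#' @export
conv2d_backward <- function(d_out, params, cache) {
  kd <- dim(params$kernels)
  n <- cache$in_dim[4]
  g <- as_batch(d_out)
  if (!all(dim(g) == c(cache$oh, cache$ow, kd[4], n)))
    stop("gradient shape does not match cached forward state")
  gm <- matrix(aperm(g, c(3, 1, 2, 4)), nrow = kd[4])  # cout x (oh*ow*n)
  dW <- tcrossprod(cache$P, gm)                        # (k*k*cin) x cout
  dP <- matrix(params$kernels, ncol = kd[4]) %*% gm    # (k*k*cin) x (oh*ow*n)
  dx <- numeric(prod(cache$in_dim))
  for (r in seq_len(nrow(cache$idx))) {                # rows have unique targets
    tgt <- cache$idx[r, ]
    dx[tgt] <- dx[tgt] + dP[r, ]
  }
  dim(dx) <- cache$in_dim
  list(d_kernels = array(dW, kd), d_biases = rowSums(gm), d_input = dx)
}

#' Average pooling forward pass
#'
#' Tiles must cover the map exactly: `(h - size) %% stride == 0` on both
#' axes, otherwise an incomplete-tile error is raised.
#'
#' @param input feature-map array `(h, w, c[, n])`.
#' @param size tile edge length.
#' @param stride step between tiles (defaults to `size`).
#' @param keep_cache keep state for [avg_pool_backward()].
#' @return Pooled array `(oh, ow, c[, n])`.
#' @export
avg_pool <- function(input, size = 2L, stride = size, keep_cache = FALSE) {
  single <- length(dim(input) %||% dim(as.matrix(input))) < 4L
  x <- as_batch(input)
  d <- dim(x)
  size <- as.integer(size); stride <- as.integer(stride)
  if (size < 1L || stride < 1L) stop("size and stride must be positive")
  if (d[1] < size || d[2] < size ||
      (d[1] - size) %% stride != 0L || (d[2] - size) %% stride != 0L)
    stop("incomplete pooling tiles: spatial dims must satisfy (dim - size) %% stride == 0")
  ti <- seq.int(1L, d[1] - size + 1L, by = stride)
  tj <- seq.int(1L, d[2] - size + 1L, by = stride)
  acc <- array(0, c(length(ti), length(tj), d[3], d[4]))
  for (di in 0:(size - 1L)) for (dj in 0:(size - 1L))
    acc <- acc + x[ti + di, tj + dj, , , drop = FALSE]
  out <- acc / (size * size)
  if (single && d[4] == 1L) dim(out) <- dim(out)[1:3]
  if (keep_cache)
    attr(out, "cache") <- list(in_dim = d, size = size, stride = stride,
                               ti = ti, tj = tj)
  out
}

#' Backward pass of [avg_pool()]
#' @param d_out gradient w.r.t. the pooled output.
#' @param cache the `"cache"` attribute from the forward pass.
#' @return Gradient w.r.t. the input, shaped like the forward input.
#' @export
avg_pool_backward <- function(d_out, cache) {
  g <- as_batch(d_out) / (cache$size^2)
  dx <- array(0, cache$in_dim)
  for (di in 0:(cache$size - 1L)) for (dj in 0:(cache$size - 1L))
    dx[cache$ti + di, cache$tj + dj, , ] <-
      dx[cache$ti + di, cache$tj + dj, , , drop = FALSE] + g
  dx
}

#' Numerically stable logistic sigmoid
#'
#' `1/(1 + exp(-x))` elementwise; saturates without overflow for |x| far
#' beyond 500.
#' @param x numeric scalar, vector, matrix or array.
#' @return Same shape as `x`, values in (0, 1).
#' @export
sigmoid <- function(x) {
  out <- stats::plogis(x)
  dim(out) <- dim(x)
  out
}

# Gradient through sigmoid given its output s and upstream gradient g.
sigmoid_backward <- function(g, s) g * s * (1 - s)

#' Dense layer forward pass
#'
#' @param input numeric vector of length `in_dim`, or an `in_dim x n` matrix
#'   of column vectors.
#' @param params a [dense_layer_params()] object.
#' @return `weights %*% input + biases`, a vector (vector input) or
#'   `out_dim x n` matrix.
#' @export
dense_forward <- function(input, params) {
  x <- if (is.matrix(input)) input else matrix(input, ncol = 1L)
  if (nrow(x) != ncol(params$weights))
    stop(sprintf("dense input length %d does not match in_dim %d",
                 nrow(x), ncol(params$weights)))
  out <- params$weights %*% x + params$biases
  if (is.matrix(input)) out else drop(out)
}

# Backward for a dense layer; x is the cached input matrix (in_dim x n).
dense_backward <- function(d_out, params, x) {
  g <- if (is.matrix(d_out)) d_out else matrix(d_out, ncol = 1L)
  list(d_weights = tcrossprod(g, x),
       d_biases = rowSums(g),
       d_input = crossprod(params$weights, g))
}

#' Softmax probabilities and cross-entropy loss
#'
#' Shift-invariant softmax followed by `-log p[label]`.  Labels are 0-based
#' class indices (0 = healthy, 1 = COPD by repo convention).
#'
#' @param logits numeric vector (one sample) or `C x n` matrix.
#' @param labels integer class index in `0:(C-1)`, one per sample.
#' @return list with `probabilities` (same shape as `logits`), `loss`
#'   (mean cross-entropy over the batch) and `d_logits` (gradient of the
#'   mean loss).
#' @export
softmax_xent <- function(logits, labels) {
  z <- if (is.matrix(logits)) logits else matrix(logits, ncol = 1L)
  n <- ncol(z); C <- nrow(z)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("one label per sample required")
  if (any(labels < 0L | labels >= C)) stop("label out of range")
  z <- z - rep(apply(z, 2L, max), each = C)
  e <- exp(z)
  p <- e / rep(colSums(e), each = C)
  pick <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[pick], .Machine$double.xmin)))
  d <- p
  d[pick] <- d[pick] - 1
  d <- d / n
  if (!is.matrix(logits)) { p <- drop(p); d <- drop(d) }
  list(probabilities = p, loss = loss, d_logits = d)
}

# Glorot/uniform initialization draw in [-r, r], r = sqrt(6/(fan_in+fan_out)).
# Uses the current RNG stream; callers wrap in withr::with_seed().
glorot_uniform <- function(dims, fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -r, r), dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
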