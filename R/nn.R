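#' @useDynLib wavesr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- tensor helpers ---------------------------------------------------------
# Feature maps are arrays [H, W, C, N]; a 3-d array is promoted to batch 1.

as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 3L) x <- array(x, c(d, 1L))
  else if (length(d) != 4L) stop("feature map must have 2-4 dimensions")
  x
}

# ---- activations ------------------------------------------------------------
# relu/tanh are fused into the C++ convolution kernels; only the gating
# nonlinearity lives here.

#' Hard-sigmoid gating nonlinearity
#'
#' Piecewise-linear sigmoid approximation `clamp((x + 3) / 6, 0, 1)`
#' (the MobileNetV3 convention), used to normalize the spatial attention
#' map into `[0, 1]`.
#'
#' @param x numeric vector/array.
#' @return values in `[0, 1]`, same shape as `x`.
#' @export
hard_sigmoid <- function(x) pmin(pmax((x + 3) / 6, 0), 1)

hard_sigmoid_grad <- function(x) as.numeric(x > -3 & x < 3) / 6

# ---- convolution wrappers ---------------------------------------------------
# The C++ kernels fuse the element-wise activation into the convolution and
# can cache the im2col matrix in a numbered slot for reuse by the matching
# backward call (training-loop fast path; -1 disables caching).

act_code <- function(act) {
  switch(act, linear = 0L, relu = 1L, tanh = 2L,
         stop("unknown activation '", act, "'"))
}

conv2d <- function(x, w, b, act = "linear", cache = -1L) {
  cpp_conv2d_fwd(x, w, b, act_code(act), cache)
}
conv2d_bwd <- function(x, w, y, dy, act = "linear", cache = -1L) {
  cpp_conv2d_bwd(x, w, y, dy, act_code(act), cache)
}
dwconv2d <- function(x, w, act = "linear") {
  cpp_dwconv2d_fwd(x, w, act_code(act))
}
dwconv2d_bwd <- function(x, w, y, dy, act = "linear") {
  cpp_dwconv2d_bwd(x, w, y, dy, act_code(act))
}

# ---- pixel shuffle ----------------------------------------------------------

#' Sub-pixel rearrangement (pixel shuffle)
#'
#' Maps an `[H, W, s^2 * C, N]` tensor to `[s*H, s*W, C, N]` by moving the
#' `s^2` channel groups onto an `s x s` sub-pixel grid. The rearrangement
#' is a bijection on values: input channel `c * s^2 + dy * s + dx`
#' (0-based) supplies output pixel offsets `(dy, dx)` of output channel
#' `c`.
#'
#' @param x feature array `[H, W, s^2 * C, N]` (3-d input treated as batch 1).
#' @param scale integer upscaling factor (at least 2).
#' @return array `[s*H, s*W, C, N]`.
#' @export
pixel_shuffle <- function(x, scale) {
  x <- as_feature_map(x)
  s <- as.integer(scale)
  if (length(s) != 1 || is.na(s) || s < 2) {
    stop("pixel shuffle requires an integer scale of at least 2")
  }
  d <- dim(x)
  if (d[3] %% (s * s) != 0) {
    stop("channel count ", d[3], " is not a multiple of scale^2 = ", s * s)
  }
  cc <- d[3] %/% (s * s)
  # channel index decomposes as (dx slow, dy fast) within each output channel
  xr <- array(x, c(d[1], d[2], s, s, cc, d[4]))   # H, W, dy, dx, C, N
  out <- aperm(xr, c(3, 1, 4, 2, 5, 6))           # dy, H, dx, W, C, N
  array(out, c(s * d[1], s * d[2], cc, d[4]))
}

pixel_unshuffle <- function(x, scale) {
  x <- as_feature_map(x)
  s <- as.integer(scale)
  d <- dim(x)
  stopifnot(d[1] %% s == 0, d[2] %% s == 0)
  xr <- array(x, c(s, d[1] %/% s, s, d[2] %/% s, d[3], d[4]))
  out <- aperm(xr, c(2, 4, 1, 3, 5, 6))
  array(out, c(d[1] %/% s, d[2] %/% s, s * s * d[3], d[4]))
}

# ---- channel pooling --------------------------------------------------------

channel_avg_pool <- function(x) {
  d <- dim(x)
  m <- rowMeans(array(aperm(x, c(1, 2, 4, 3)), c(d[1] * d[2] * d[4], d[3])))
  array(aperm(array(m, c(d[1], d[2], d[4], 1L)), c(1, 2, 4, 3)),
        c(d[1], d[2], 1L, d[4]))
}

channel_max_pool <- function(x) {
  d <- dim(x)
  out <- x[, , 1L, , drop = FALSE]
  if (d[3] > 1) {
    for (c in 2:d[3]) out <- pmax(out, x[, , c, , drop = FALSE])
  }
  array(out, c(d[1], d[2], 1L, d[4]))
}

# ---- weight initialization --------------------------------------------------

# He-uniform for the ReLU path, Glorot-uniform for the Tanh path.
init_conv_w <- function(k, c_in, c_out, act) {
  fan_in <- k * k * c_in
  limit <- if (act == "tanh") sqrt(6 / (fan_in + k * k * c_out))
           else sqrt(6 / fan_in)
  array(stats::runif(k * k * c_in * c_out, -limit, limit),
        c(k, k, c_in, c_out))
}

init_dw_w <- function(k, c, act) {
  limit <- if (act == "tanh") sqrt(6 / (2 * k * k)) else sqrt(6 / (k * k))
  array(stats::runif(k * k * c, -limit, limit), c(k, k, c))
}
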