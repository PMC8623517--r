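#' Bicubic image resampling
#'
#' Separable Keys bicubic interpolation (a = -0.5) with edge clamping.
#' When shrinking, the kernel is widened by the scale factor (antialiasing),
#' matching the convention of the common image-processing toolboxes, so the
#' low-resolution inputs generated for training follow the standard bicubic
#' degradation protocol.
#'
#' @param image numeric matrix.
#' @param out_h,out_w output size in pixels.
#' @return numeric matrix of size `out_h` x `out_w`.
#' @export
bicubic_resize <- function(image, out_h, out_w) {
  image <- as_pixel_matrix(image)
  wr <- resample_weights(nrow(image), out_h)
  wc <- resample_weights(ncol(image), out_w)
  wr %*% image %*% t(wc)
}

# Keys cubic kernel, a = -0.5
cubic_kernel <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# Dense 1-D resampling operator (n_out x n_in), rows normalized to sum 1.
# Output sample i (0-based) is centred at source coordinate
# (i + 0.5) * n_in / n_out - 0.5; out-of-range taps clamp to the edge.
resample_weights <- function(n_in, n_out) {
  stopifnot(n_in >= 1, n_out >= 1)
  scale <- n_in / n_out
  kw <- max(scale, 1) # kernel stretch: antialias on downscale only
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    u <- (i - 0.5) * scale - 0.5 # 0-based source centre
    lo <- floor(u - 2 * kw) + 1
    hi <- ceiling(u + 2 * kw) - 1
    taps <- lo:hi
    vals <- cubic_kernel((taps - u) / kw)
    cols <- pmin(pmax(taps, 0), n_in - 1) + 1 # clamp, back to 1-based
    for (k in seq_along(taps)) {
      w[i, cols[k]] <- w[i, cols[k]] + vals[k]
    }
    w[i, ] <- w[i, ] / sum(w[i, ])
  }
  w
}

#' Bicubic upscale/downscale by an integer factor
#'
#' Convenience wrappers around [bicubic_resize()] for the exact integer
#' scale factors the super-resolution model supports.
#'
#' @param image numeric matrix.
#' @param scale integer factor (2, 3 or 4).
#' @return resized matrix.
#' @export
bicubic_upscale <- function(image, scale) {
  scale <- check_scale(scale)
  bicubic_resize(image, nrow(image) * scale, ncol(image) * scale)
}

#' @rdname bicubic_upscale
#' @export
bicubic_downscale <- function(image, scale) {
  scale <- check_scale(scale)
  if (nrow(image) %% scale != 0 || ncol(image) %% scale != 0) {
    stop("image size ", nrow(image), "x", ncol(image),
         " is not divisible by scale ", scale)
  }
  bicubic_resize(image, nrow(image) %/% scale, ncol(image) %/% scale)
}

check_scale <- function(scale) {
  if (length(scale) != 1 || !scale %in% c(2, 3, 4)) {
    stop("scale must be 2, 3 or 4")
  }
  as.integer(scale)
}

clip_pixels <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)
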