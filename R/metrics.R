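#' Peak signal-to-noise ratio for 8-bit images
#'
#' `PSNR = 10 log10(255^2 / MSE)` with the mean squared error taken over
#' all pixels. Both images are interpreted on the 8-bit scale (peak 255)
#' regardless of their actual dynamic range. Identical images have zero
#' MSE; the function then returns `Inf` as an explicit sentinel rather
#' than capping the value.
#'
#' @param reference,test numeric matrices of identical size, 8-bit scale.
#' @return PSNR in decibels (`Inf` for identical images).
#' @export
psnr <- function(reference, test) {
  check_same_shape(reference, test)
  err <- mse(reference, test)
  if (err == 0) {
    return(Inf)
  }
  10 * log10(255^2 / err)
}

#' Mean squared error
#'
#' @param reference,test numeric matrices of identical size.
#' @return mean of squared pixel differences.
#' @export
mse <- function(reference, test) {
  check_same_shape(reference, test)
  mean((reference - test)^2)
}

#' Structural similarity index (SSIM)
#'
#' Mean structural similarity over 11x11 Gaussian-weighted local windows
#' (sigma 1.5), with the standard stabilizing constants
#' `c1 = (0.01 * 255)^2` and `c2 = (0.03 * 255)^2`:
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'                   {(\mu_x^2 + \mu_y^2 + c_1)(\sigma_x^2 + \sigma_y^2 + c_2)}}
#' Windows are restricted to positions fully inside the image (valid
#' region). The statistic equals 1 exactly for identical images and can be
#' negative for anticorrelated patches; no clamping is applied.
#'
#' @param reference,test numeric matrices of identical size (at least
#'   11x11), 8-bit scale.
#' @return mean SSIM (unitless, at most 1).
#' @export
ssim <- function(reference, test) {
  check_same_shape(reference, test)
  if (nrow(reference) < 11 || ncol(reference) < 11) {
    stop("SSIM needs images of at least 11x11, got ",
         nrow(reference), "x", ncol(reference))
  }
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  gr <- gaussian_valid_operator(nrow(reference))
  gc <- gaussian_valid_operator(ncol(reference))
  smooth <- function(m) gr %*% m %*% t(gc)
  mu_x <- smooth(reference)
  mu_y <- smooth(test)
  # Gaussian-weighted (population) moments, per the original SSIM paper
  var_x <- smooth(reference^2) - mu_x^2
  var_y <- smooth(test^2) - mu_y^2
  cov_xy <- smooth(reference * test) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)
  den <- (mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2)
  mean(num / den)
}

#' Full quality report for an image pair
#'
#' @param reference,test numeric matrices of identical size, 8-bit scale.
#' @return one-row data.frame with columns `mse`, `psnr`, `ssim`.
#' @export
evaluate_quality <- function(reference, test) {
  data.frame(
    mse = mse(reference, test),
    psnr = psnr(reference, test),
    ssim = ssim(reference, test)
  )
}

# Valid-region 1-D Gaussian smoothing operator ((n-10) x n), 11 taps,
# sigma 1.5, taps normalized to sum 1.
gaussian_valid_operator <- function(n) {
  taps <- exp(-((-5:5)^2) / (2 * 1.5^2))
  taps <- taps / sum(taps)
  m <- matrix(0, n - 10, n)
  for (i in seq_len(n - 10)) {
    m[i, i:(i + 10)] <- taps
  }
  m
}

check_same_shape <- function(reference, test) {
  if (!identical(dim(reference), dim(test))) {
    stop("images differ in shape: ", paste(dim(reference), collapse = "x"),
         " vs ", paste(dim(test), collapse = "x"))
  }
  invisible(NULL)
}
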