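#' Parameters for the synthetic chest phantom
#'
#' The phantom emulates the gross statistics of a chest radiograph that the
#' frequency-separated network design relies on: a bright, smoothly varying
#' mediastinum/background (strong low-frequency structure), two darker
#' elliptical lung fields, curved periodic rib bands, and optional Gaussian
#' noise. It makes every module testable without any external dataset; it
#' is not an anatomical simulation.
#'
#' @param size image side length in pixels (square), at least 64.
#' @param n_rib_bands number of rib band periods across the image height.
#' @param rib_contrast peak rib band amplitude in gray levels.
#' @param lung_centers 2x2 matrix of ellipse centres as (x, y) fractions of
#'   the image size, one row per lung field.
#' @param lung_axes ellipse semi-axes (x, y) as fractions of the image size.
#' @param lung_depth gray-level drop inside the lung fields.
#' @param gradient_slope vertical background gradient in gray levels per
#'   image height.
#' @param noise_sigma standard deviation of additive Gaussian noise in gray
#'   levels (0 disables noise).
#' @param seed integer seed fixing all randomness.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(size = 256,
                           n_rib_bands = 5,
                           rib_contrast = 25,
                           lung_centers = rbind(c(0.30, 0.47), c(0.70, 0.47)),
                           lung_axes = c(0.16, 0.27),
                           lung_depth = 70,
                           gradient_slope = 55,
                           noise_sigma = 1.5,
                           seed = 1L) {
  if (size < 64) stop("phantom size must be at least 64")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  p <- list(size = as.integer(size), n_rib_bands = n_rib_bands,
            rib_contrast = rib_contrast, lung_centers = lung_centers,
            lung_axes = lung_axes, lung_depth = lung_depth,
            gradient_slope = gradient_slope, noise_sigma = noise_sigma,
            seed = as.integer(seed))
  class(p) <- "phantom_params"
  p
}

#' Generate a chest-phantom image
#'
#' Deterministic per seed: the same `phantom_params` always yield a
#' bit-identical 8-bit image. The continuous background gradient guarantees
#' a rich gray-level histogram, and with `noise_sigma = 0` the image is
#' piecewise smooth so the diagonal wavelet sub-band is sparse — the regime
#' the detail path of the network is designed for.
#'
#' @param params a [phantom_params()] object.
#' @return integer-valued numeric matrix in `[0, 255]` (size x size).
#' @export
make_phantom <- function(params = phantom_params()) {
  n <- params$size
  xx <- matrix(rep((seq_len(n) - 0.5) / n, each = n), n, n)  # column coord
  yy <- matrix(rep((seq_len(n) - 0.5) / n, times = n), n, n) # row coord

  # bright smooth background: vertical gradient plus a gentle radial falloff
  img <- 185 + params$gradient_slope * (yy - 0.5) -
    45 * ((xx - 0.5)^2 + (yy - 0.55)^2)

  # dark elliptical lung fields with a soft (but narrow) edge
  lung_mask <- matrix(0, n, n)
  for (i in seq_len(nrow(params$lung_centers))) {
    cx <- params$lung_centers[i, 1]
    cy <- params$lung_centers[i, 2]
    e <- ((xx - cx) / params$lung_axes[1])^2 +
      ((yy - cy) / params$lung_axes[2])^2
    lung_mask <- pmax(lung_mask, clip_pixels((1 - e) / 0.08, 0, 1))
  }
  img <- img - params$lung_depth * lung_mask

  # curved periodic rib bands, strongest over the lung fields
  if (params$n_rib_bands > 0 && params$rib_contrast > 0) {
    phase <- params$n_rib_bands * (yy + 0.10 * sin(pi * xx))
    ribs <- params$rib_contrast * cos(2 * pi * phase)
    img <- img + ribs * (0.25 + 0.75 * lung_mask)
  }

  if (params$noise_sigma > 0) {
    withr_seed <- params$seed
    old <- .Random.seed_exists()
    set.seed(withr_seed)
    img <- img + matrix(stats::rnorm(n * n, sd = params$noise_sigma), n, n)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  round(clip_pixels(img))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

#' Build a synthetic LR/HR patch dataset
#'
#' Generates `n_images` phantoms (seeds `params$seed + 0:(n_images-1)`),
#' cuts each into aligned HR crops on a regular grid, pairs every crop with
#' its bicubic downscale, and shuffles the pairs under `params$seed`.
#'
#' @param n_images number of phantom images.
#' @param params a [phantom_params()] object (its seed anchors the run).
#' @param scale super-resolution factor (2, 3 or 4).
#' @param patch_size HR crop side length (default 48).
#' @param stride grid stride between crops (default 24, i.e. 50% overlap).
#' @return list of patch pairs, each `list(lr = , hr = )` with `lr` of side
#'   `patch_size / scale`.
#' @export
make_dataset <- function(n_images, params = phantom_params(), scale = 2,
                         patch_size = 48, stride = 24) {
  stopifnot(n_images >= 1)
  scale <- check_scale(scale)
  cfg <- train_config(scale = scale, patch_size = patch_size,
                      patch_stride = stride, seed = params$seed)
  pairs <- list()
  for (i in seq_len(n_images)) {
    p_i <- params
    p_i$seed <- params$seed + i - 1L
    pairs <- c(pairs, extract_patches(make_phantom(p_i), cfg))
  }
  old <- .Random.seed_exists()
  set.seed(params$seed)
  pairs <- pairs[sample.int(length(pairs))]
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  pairs
}
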