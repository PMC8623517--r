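#' One-level 2D stationary (undecimated) Haar wavelet transform
#'
#' Decomposes a grayscale image into four same-sized coefficient planes:
#' the approximate sub-band `A` (separable low-pass) and the horizontal,
#' vertical and diagonal detail sub-bands `H`, `V`, `D`. The transform is
#' undecimated: every plane has the spatial size of the input, which makes
#' it shift-invariant and imposes no parity constraint on the image size.
#'
#' Boundaries are handled by periodic (circular) extension, the convention
#' under which every coefficient is a signed half-sum of a 2x2 pixel window
#' \deqn{A = (a+b+c+d)/2,\quad H = (a+b-c-d)/2,\quad
#'       V = (a-b+c-d)/2,\quad D = (a-b-c+d)/2}
#' with `a` the current pixel, `b` its right neighbour, `c` the pixel below
#' and `d` the diagonal neighbour (wrapping at the edges). Consequences used
#' throughout the package: for pixels in `[lo, hi]` the `A` plane lies in
#' `[2*lo, 2*hi]` and the detail planes in `[-(hi-lo), hi-lo]`; the detail
#' planes sum to zero exactly, and `mean(A)` is twice the image mean.
#'
#' @param image numeric matrix (height x width), at least 2x2.
#' @return An object of class `wavelet_bands`: a list with matrices
#'   `A`, `H`, `V`, `D` (each the size of `image`) and `level = 1`.
#' @seealso [iswt2_level1()] for the inverse, [subband_stats()] for
#'   per-band summaries.
#' @examples
#' b <- swt2_level1(matrix(c(100, 30, 50, 20), 2, 2))
#' b$A[1, 1] # 100
#' @export
swt2_level1 <- function(image) {
  image <- as_pixel_matrix(image)
  h <- nrow(image)
  w <- ncol(image)
  if (h < 2 || w < 2) {
    stop("image must be at least 2x2, got ", h, "x", w)
  }
  ri <- c(seq_len(h)[-1], 1L) # i + 1 (periodic)
  ci <- c(seq_len(w)[-1], 1L) # j + 1 (periodic)
  x00 <- image
  x01 <- image[, ci, drop = FALSE]
  x10 <- image[ri, , drop = FALSE]
  x11 <- image[ri, ci, drop = FALSE]
  bands <- list(
    A = (x00 + x01 + x10 + x11) / 2,
    H = (x00 + x01 - x10 - x11) / 2,
    V = (x00 - x01 + x10 - x11) / 2,
    D = (x00 - x01 - x10 + x11) / 2,
    level = 1L
  )
  class(bands) <- "wavelet_bands"
  bands
}

#' Inverse one-level stationary Haar transform
#'
#' Reconstructs an image from the four coefficient planes. Each pixel has
#' four redundant reconstructions (one per role it plays in the 2x2 windows
#' covering it); their average is returned. For coefficient planes actually
#' produced by [swt2_level1()] the four agree and reconstruction is exact to
#' floating tolerance; for planes predicted by a network the average is the
#' least-squares-consistent inverse.
#'
#' @param bands a `wavelet_bands` object, or any list with equally shaped
#'   matrices `A`, `H`, `V`, `D`.
#' @return numeric matrix of the common plane size.
#' @export
iswt2_level1 <- function(bands) {
  validate_bands(bands)
  A <- bands$A; H <- bands$H; V <- bands$V; D <- bands$D
  h <- nrow(A)
  w <- ncol(A)
  di <- c(h, seq_len(h)[-h]) # i - 1 (periodic)
  li <- c(w, seq_len(w)[-w]) # j - 1 (periodic)
  r_a <- (A + H + V + D) / 2                        # pixel as 'a' at (i, j)
  r_b <- (A + H - V - D) / 2                        # as 'b' at (i, j-1)
  r_c <- (A - H + V - D) / 2                        # as 'c' at (i-1, j)
  r_d <- (A - H - V + D) / 2                        # as 'd' at (i-1, j-1)
  (r_a + r_b[, li, drop = FALSE] + r_c[di, , drop = FALSE] +
     r_d[di, li, drop = FALSE]) / 4
}

#' Split wavelet bands into network inputs
#'
#' Rearranges a `wavelet_bands` object into the two tensors the separated
#' network paths consume: the approximate plane as a 1-channel array and the
#' three detail planes stacked as a 3-channel array in the fixed order
#' H, V, D.
#'
#' @param bands a `wavelet_bands` object.
#' @return list with `approx` (h x w x 1 array) and `detail` (h x w x 3
#'   array, channels H, V, D).
#' @export
split_bands <- function(bands) {
  validate_bands(bands)
  h <- nrow(bands$A)
  w <- ncol(bands$A)
  list(
    approx = array(bands$A, dim = c(h, w, 1L)),
    detail = array(c(bands$H, bands$V, bands$D), dim = c(h, w, 3L))
  )
}

#' Reassemble wavelet bands from network outputs
#'
#' Inverse of [split_bands()]: combines a 1-channel approximate plane and a
#' 3-channel detail stack (H, V, D order) back into a `wavelet_bands`
#' object, e.g. before the inverse transform.
#'
#' @param approx h x w matrix or h x w x 1 array.
#' @param detail h x w x 3 array with channels H, V, D.
#' @return a `wavelet_bands` object.
#' @export
merge_bands <- function(approx, detail) {
  if (length(dim(approx)) == 3L) {
    if (dim(approx)[3] != 1L) {
      stop("approx plane must have exactly 1 channel, got ", dim(approx)[3])
    }
    approx <- matrix(approx, dim(approx)[1], dim(approx)[2])
  }
  approx <- as_pixel_matrix(approx)
  if (length(dim(detail)) != 3L || dim(detail)[3] != 3L) {
    stop("detail stack must be an h x w x 3 array (channels H, V, D)")
  }
  if (!all(dim(detail)[1:2] == dim(approx))) {
    stop("approx plane is ", nrow(approx), "x", ncol(approx),
         " but detail stack is ", dim(detail)[1], "x", dim(detail)[2])
  }
  bands <- list(
    A = approx,
    H = detail[, , 1L],
    V = detail[, , 2L],
    D = detail[, , 3L],
    level = 1L
  )
  class(bands) <- "wavelet_bands"
  bands
}

#' Per-band summary statistics
#'
#' Sample statistics of each coefficient plane. Under the periodic Haar
#' convention the detail means are zero (to floating tolerance) for any
#' image and `mean(A)` is twice the image mean, so these summaries are the
#' quickest check that an image has the energy concentration the separated
#' network design assumes.
#'
#' @param bands a `wavelet_bands` object.
#' @return data.frame with columns `band`, `min`, `max`, `mean`, `sd`.
#' @export
subband_stats <- function(bands) {
  validate_bands(bands)
  planes <- bands[c("A", "H", "V", "D")]
  data.frame(
    band = names(planes),
    min = vapply(planes, min, numeric(1)),
    max = vapply(planes, max, numeric(1)),
    mean = vapply(planes, mean, numeric(1)),
    sd = vapply(planes, stats::sd, numeric(1)),
    row.names = NULL
  )
}

validate_bands <- function(bands) {
  if (!all(c("A", "H", "V", "D") %in% names(bands))) {
    stop("bands must contain planes A, H, V and D")
  }
  d <- dim(bands$A)
  for (nm in c("H", "V", "D")) {
    if (!identical(dim(bands[[nm]]), d)) {
      stop("plane ", nm, " has shape ", paste(dim(bands[[nm]]), collapse = "x"),
           " but A is ", paste(d, collapse = "x"))
    }
  }
  invisible(bands)
}

as_pixel_matrix <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 2L) {
    stop("expected a 2-d matrix of pixel values")
  }
  if (!is.numeric(x)) stop("pixel values must be numeric")
  x
}
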