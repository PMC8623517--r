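#' Read a grayscale image
#'
#' Reads an 8-bit grayscale PNG or TIFF into a numeric matrix in
#' `[0, 255]`. Color images are rejected unless `to_gray = TRUE`, in which
#' case the Rec.601 luminance is taken; a gray+alpha PNG keeps its gray
#' channel. 16-bit TIFF input is rescaled to the 8-bit range with a
#' warning.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param to_gray convert color input to luminance instead of erroring.
#' @return numeric matrix with values in `[0, 255]`.
#' @export
read_grayscale <- function(path, to_gray = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits > 8) {
      warning("16-bit TIFF rescaled to the 8-bit range")
    }
  } else {
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)")
  }
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 2L) {
      img <- img[, , 1L] # gray + alpha
    } else if (to_gray) {
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      stop("image has ", nc, " channels; pass to_gray = TRUE to convert")
    }
  }
  round(img * 255)
}

#' Write a grayscale image
#'
#' Writes a `[0, 255]` matrix as an 8-bit grayscale PNG or TIFF (chosen by
#' the file extension). Values are clipped and rounded.
#'
#' @param image numeric matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return the path, invisibly.
#' @export
write_grayscale <- function(image, path) {
  image <- round(clip_pixels(as_pixel_matrix(image))) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)")
  }
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the full network configuration, training
#' configuration and history alongside the weights, so a reloaded model
#' reproduces identical forward outputs.
#'
#' @param model a `wfsan_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the restored `wfsan_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, "wfsan_model")) stop("not a wfsan_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "wfsan_model") || is.null(model$params) ||
      is.null(model$config)) {
    stop("file does not contain a valid model checkpoint")
  }
  model
}
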