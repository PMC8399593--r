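# Raster I/O. Images are held in memory as base arrays of integers 0-255:
# height x width x 3 for RGB, height x width matrices for grayscale rasters,
# and 0/1 integer matrices for label masks (stored on disk as {0, 255} PNGs).

#' Read an RGB fundus image from PNG
#'
#' @param path PNG file path.
#' @return height x width x 3 array of integers in 0-255 (RGB order).
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) stop("expected a 3-channel image", call. = FALSE)
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]  # drop alpha
  round(x * 255)
}

#' Write an RGB image to PNG
#'
#' @param image height x width x 3 array, integers 0-255.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(image, path) {
  check_intensities(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a binary label mask from PNG
#'
#' Any strictly positive pixel is treated as `Neo`.
#'
#' @param path PNG file path (8-bit grayscale, values {0, 255}).
#' @return height x width integer matrix, 1 = Neo, 0 = NotNeo.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- matrix(as.integer(x > 0.5), nrow(x), ncol(x))
  m
}

#' Write a binary label mask to PNG
#'
#' @param mask height x width matrix of 0/1.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  assert_that(all(mask %in% c(0L, 1L)), "mask must be binary 0/1")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a grayscale raster from PNG
#'
#' @param path PNG file path.
#' @return height x width matrix of integers 0-255.
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  round(x * 255)
}

#' Write a grayscale raster to PNG
#'
#' @param gray height x width matrix, integers 0-255.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gray_png <- function(gray, path) {
  check_intensities(gray, "gray raster")
  png::writePNG(gray / 255, path)
  invisible(path)
}

#' Save a trained model checkpoint
#'
#' Stores the network parameters together with the declarative layer plan they
#' were built from, so a checkpoint is self-describing.
#'
#' @param model a model as returned by [init_network()] or [train_network()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  assert_that(inherits(model, "neovaseg_model"), "model must be a neovaseg_model")
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return The model object.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "neovaseg_model")) {
    stop("file is not a neovaseg model checkpoint", call. = FALSE)
  }
  model
}
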