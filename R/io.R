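# Grayscale TIFF input/output for projection images and label masks.

#' Write a grayscale image to TIFF
#'
#' 8- or 16-bit grayscale, lossless. `projection_image` pixels are written
#' at their metadata bit depth; plain integer matrices at `bit_depth`.
#'
#' @param image a `projection_image` or an integer matrix.
#' @param path output file path.
#' @param bit_depth sample depth for plain matrices (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 16L) {
  if (inherits(image, "projection_image")) {
    bit_depth <- image$meta$bit_depth %||% bit_depth
    pix <- image$pixels
  } else if (is.matrix(image)) {
    pix <- image
  } else stop_config("`image` must be a projection_image or a matrix")
  if (!bit_depth %in% c(8L, 16L))
    stop_config("`bit_depth` must be 8 or 16")
  top <- 2^bit_depth - 1
  if (any(pix < 0) || any(pix > top))
    stop_config("pixel values exceed the %d-bit range", bit_depth)
  tiff::writeTIFF(pix / top, path, bits.per.sample = bit_depth)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a grayscale TIFF as a projection image
#'
#' @param path TIFF file path.
#' @return a `projection_image` with integer pixels and the sample depth in
#'   `meta$bit_depth`. RGB input is rejected with instructions to convert.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop_config("image file does not exist: %s", path)
  x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(x)) == 3L)
    stop_config(
      "%s has %d channels; convert to single-channel grayscale first",
      path, dim(x)[3])
  bits <- attr(x, "bits.per.sample") %||% 16L
  pix <- matrix(as.integer(x), nrow(x), ncol(x))
  projection_image(pix, meta = list(bit_depth = as.integer(bits)))
}

#' Write a region label mask as an 8-bit TIFF
#'
#' Labels are stored directly as 8-bit values (0 background, 1 normal,
#' 2 tumor).
#'
#' @param mask integer matrix of labels in 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask <= 255))
  tiff::writeTIFF(mask / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit label mask
#'
#' @param path TIFF file path.
#' @return integer matrix of labels.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  img$pixels
}
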