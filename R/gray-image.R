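#' Single-channel image container
#'
#' A `gray_image` wraps a numeric pixel matrix together with its nominal
#' bit depth and (optionally) the physical pixel pitch in nanometers.
#' Rows index the y (vertical) axis and columns the x (horizontal) axis.
#' Bit depths 8 and 16 denote integer-range sensor data and must contain
#' non-negative intensities within the representable range; bit depth 32
#' marks a floating-point working image with no range restriction (used
#' for intermediate results such as unrescaled reintegration output).
#'
#' @param pixels numeric matrix of intensities, at least 8 x 8.
#' @param bit_depth one of 8, 16, 32.
#' @param pixel_size_nm optional positive physical pixel size in nm.
#' @return An object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0:63, 8, 8), bit_depth = 8)
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, bit_depth = 16L, pixel_size_nm = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    natimg_error("pixels must be a numeric matrix", "invalid_input")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    natimg_error("image must be at least 8 x 8 pixels", "invalid_input")
  if (!all(is.finite(pixels)))
    natimg_error("all intensities must be finite", "invalid_input")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L, 32L))
    natimg_error("bit_depth must be 8, 16 or 32", "invalid_input")
  if (bit_depth %in% c(8L, 16L)) {
    if (any(pixels < 0) || any(pixels > 2^bit_depth - 1))
      natimg_error(
        sprintf("intensities outside [0, %d] for bit depth %d",
                2^bit_depth - 1, bit_depth), "invalid_input")
  }
  if (!is.null(pixel_size_nm)) {
    pixel_size_nm <- as.numeric(pixel_size_nm)
    if (length(pixel_size_nm) != 1L || !is.finite(pixel_size_nm) ||
        pixel_size_nm <= 0)
      natimg_error("pixel_size_nm must be a positive scalar", "invalid_input")
  }
  structure(
    list(pixels = unname(pixels), bit_depth = bit_depth,
         pixel_size_nm = pixel_size_nm),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              if (is.null(x$pixel_size_nm)) ""
              else sprintf(", %.4g nm/px", x$pixel_size_nm)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

# Accept either a gray_image or a bare matrix in user-facing entry points.
as_gray_image <- function(x, bit_depth = 16L) {
  if (is_gray_image(x)) return(x)
  if (is.matrix(x) && is.numeric(x)) return(gray_image(x, bit_depth = bit_depth))
  natimg_error("expected a gray_image or numeric matrix", "invalid_input")
}

#' Convert an image to 8-bit by linear min-max rescaling
#'
#' Naturalness statistics re-use a prior estimated from 8-bit natural
#' images, so every image is brought to a common 8-bit scale first.
#' Intensities are mapped linearly from the input's observed
#' `[min, max]` to `[0, 255]` and rounded half-to-even.  A constant image
#' (zero dynamic range) maps to all zeros.  8-bit inputs are returned
#' unchanged.
#'
#' @param image a [gray_image()] (or numeric matrix).
#' @return An 8-bit `gray_image`.
#' @export
to_gray8 <- function(image) {
  image <- as_gray_image(image)
  if (image$bit_depth == 8L) return(image)
  p <- image$pixels
  lo <- min(p); hi <- max(p)
  out <- if (hi > lo) round((p - lo) / (hi - lo) * 255) else p * 0
  gray_image(out, bit_depth = 8L, pixel_size_nm = image$pixel_size_nm)
}

#' Read a grayscale TIFF or PNG image
#'
#' Single-channel 8- or 16-bit images only; multi-channel files are
#' rejected because the naturalness statistics are defined on grayscale
#' data.
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @param pixel_size_nm optional pixel size to attach, in nanometers.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, pixel_size_nm = NULL) {
  if (!file.exists(path)) natimg_error(paste("no such file:", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(raw)) == 3L)
      natimg_error("multi-channel image: grayscale input required",
                   "invalid_input")
    bits <- if (max(raw) > 255) 16L else 8L
    gray_image(raw, bit_depth = bits, pixel_size_nm = pixel_size_nm)
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3L)
      natimg_error("multi-channel image: grayscale input required",
                   "invalid_input")
    # readPNG rescales to [0, 1]; store at 16-bit resolution
    gray_image(round(raw * 65535), bit_depth = 16L,
               pixel_size_nm = pixel_size_nm)
  } else {
    natimg_error("unsupported image format (use TIFF or PNG)", "invalid_input")
  }
}

#' Write a grayscale image to TIFF or PNG
#'
#' @param image a [gray_image()].
#' @param path destination path; format chosen from the extension.
#' @return Invisibly, `path`.
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  depth <- if (image$bit_depth == 8L) 8L else 16L
  maxv <- 2^depth - 1
  p <- image$pixels
  lo <- min(p); hi <- max(p)
  if (lo < 0 || hi > maxv) {  # float working image: rescale into range
    p <- if (hi > lo) (p - lo) / (hi - lo) * maxv else p * 0
  }
  unit <- round(p) / maxv
  ok <- if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(unit, path, bits.per.sample = depth)
  } else if (ext == "png") {
    png::writePNG(unit, path)
  } else {
    natimg_error("unsupported image format (use TIFF or PNG)", "invalid_input")
  }
  invisible(path)
}
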