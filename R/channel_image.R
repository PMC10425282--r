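#' Single-channel fluorescence image
#'
#' A `channel_image` wraps one co-registered grayscale fluorescence channel
#' together with its biological role. Intensities are non-negative integers on
#' the scale implied by `bit_depth`.
#'
#' @param pixels Integer matrix of intensities (rows x cols), all values in
#'   `[0, 2^bit_depth - 1]`.
#' @param role Channel role: `"DNA"` (nucleic-acid stain, used for cell
#'   counting), `"MEMBRANE"` (whole-cell outline) or `"PHA"` (storage
#'   granules).
#' @param bit_depth Bits per sample, 8 or 16.
#' @param pixel_size Optional physical pixel edge length in micrometres per
#'   pixel; `NULL` when unknown (all downstream fractions are dimensionless,
#'   so it is informational only).
#'
#' @return An object of class `channel_image` with fields `pixels`,
#'   `bit_depth`, `role`, `pixel_size`.
#' @examples
#' img <- channel_image(matrix(0L, 8, 8), role = "DNA")
#' dim(img$pixels)
#' @export
channel_image <- function(pixels, role = c("DNA", "MEMBRANE", "PHA"),
                          bit_depth = 8L, pixel_size = NULL) {
  role <- match.arg(role)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("image must be at least 1x1")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels)) stop("`pixels` contains missing values")
  maxval <- 2L^bit_depth - 1L
  if (min(pixels) < 0L || max(pixels) > maxval)
    stop("intensities must lie in [0, ", maxval, "]")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth), role = role,
         pixel_size = pixel_size),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px, %d-bit, range [%d, %d]\n",
              x$role, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Rescale a channel image to the 8-bit range
#'
#' Linearly maps the image's own min-max intensity range onto `[0, 255]`
#' (rounding to nearest). A constant image maps to all zeros. 8-bit images are
#' returned unchanged; Bernsen thresholding applies this to 16-bit input
#' because the low-contrast cut is defined on the 8-bit scale.
#'
#' @param img A [channel_image()].
#' @return A `channel_image` with `bit_depth = 8`.
#' @export
rescale_to_8bit <- function(img) {
  stopifnot(inherits(img, "channel_image"))
  if (img$bit_depth == 8L) return(img)
  px <- img$pixels
  lo <- min(px); hi <- max(px)
  out <- if (hi == lo) matrix(0L, nrow(px), ncol(px))
         else matrix(as.integer(round((px - lo) * 255 / (hi - lo))),
                     nrow(px), ncol(px))
  channel_image(out, role = img$role, bit_depth = 8L,
                pixel_size = img$pixel_size)
}

#' Read a grayscale TIFF as a channel image
#'
#' Reads an 8- or 16-bit single-channel TIFF. For a multi-page TIFF, `page`
#' selects which page holds the requested role.
#'
#' @param path Path to a TIFF file.
#' @param role Channel role, see [channel_image()].
#' @param page 1-based page index for multi-page TIFFs.
#' @param pixel_size Optional micrometres per pixel.
#' @return A [channel_image()].
#' @export
read_channel_tiff <- function(path, role, page = 1L, pixel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (page < 1L || page > length(pages))
    stop("page ", page, " out of range for ", path)
  px <- pages[[page]]
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] != 1L) stop("expected a single-channel grayscale TIFF: ", path)
    px <- px[, , 1L]
  }
  px <- matrix(as.integer(px), nrow(px), ncol(px))  # drop TIFF metadata attrs
  channel_image(px, role = role, bit_depth = as.integer(bits),
                pixel_size = pixel_size)
}

#' Write a channel image or mask to TIFF
#'
#' `write_channel_tiff()` writes integer intensities at the image's bit depth.
#' `write_mask_tiff()` writes a binary mask or integer label image as 8-bit
#' (labels above 255 are written 16-bit).
#'
#' @param img A [channel_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(img, path) {
  stopifnot(inherits(img, "channel_image"))
  maxval <- 2^img$bit_depth - 1
  tiff::writeTIFF(img$pixels / maxval, path,
                  bits.per.sample = img$bit_depth, compression = "none")
  invisible(path)
}

#' @param x A logical mask matrix, integer label matrix, [binary_mask()] or
#'   [particle_set()] (its label image).
#' @rdname write_channel_tiff
#' @export
write_mask_tiff <- function(x, path) {
  if (inherits(x, "binary_mask")) x <- x$pixels
  if (inherits(x, "particle_set")) x <- x$label_image
  m <- x
  storage.mode(m) <- "integer"
  bits <- if (max(m) > 255L) 16L else 8L
  tiff::writeTIFF(m / (2^bits - 1), path, bits.per.sample = bits,
                  compression = "none")
  invisible(path)
}
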