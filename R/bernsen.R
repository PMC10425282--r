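#' Bernsen thresholding parameters
#'
#' Parameters of the Bernsen adaptive local threshold with a circular window.
#' Defaults follow the de-facto reference implementation of the method in the
#' common image-analysis toolchain: window radius 15 px, contrast threshold
#' 15, low-contrast cut 128, all on the 8-bit intensity scale.
#'
#' @param radius Window radius in pixels (integer >= 1). Pixels whose centre
#'   lies within Euclidean distance `radius` of the current pixel form the
#'   window; windows are clipped at image borders.
#' @param contrast_threshold Local contrast (window max - min) below which a
#'   region is considered low-contrast.
#' @param low_contrast_cut Intensity splitting low-contrast regions into
#'   all-object (window midgray >= cut) versus all-background.
#' @return An object of class `bernsen_params`.
#' @export
bernsen_params <- function(radius = 15L, contrast_threshold = 15L,
                           low_contrast_cut = 128L) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("`radius` must be an integer >= 1")
  if (contrast_threshold < 0) stop("`contrast_threshold` must be >= 0")
  if (low_contrast_cut < 0 || low_contrast_cut > 255)
    stop("`low_contrast_cut` must lie in [0, 255]")
  structure(list(radius = radius,
                 contrast_threshold = as.integer(contrast_threshold),
                 low_contrast_cut = as.integer(low_contrast_cut)),
            class = "bernsen_params")
}

#' Binary mask
#'
#' Result of thresholding a [channel_image()]: a logical object/background
#' matrix of the same dimensions, carrying its provenance (source role and
#' thresholding parameters).
#'
#' @param pixels Logical matrix (`TRUE` = object).
#' @param provenance List describing how the mask was produced.
#' @return An object of class `binary_mask` with fields `pixels`,
#'   `provenance`.
#' @export
binary_mask <- function(pixels, provenance = list()) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix")
  structure(list(pixels = pixels, provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d object px (%.1f%%)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

#' Bernsen adaptive local threshold
#'
#' Binarizes a fluorescence channel with Bernsen's local method: for each
#' pixel the extrema of the intensities in a circular window of the given
#' radius (clipped at the image border, no padding) define the local contrast
#' `max - min` and midgray `(max + min)/2`. High-contrast pixels
#' (`contrast >= contrast_threshold`) are object when their intensity strictly
#' exceeds the midgray; low-contrast windows are assigned wholesale by
#' comparing the midgray against `low_contrast_cut`. Midgray comparisons are
#' exact (integer arithmetic on `max + min`), so half-integer midgrays incur
#' no rounding.
#'
#' 16-bit input is first min-max rescaled to the 8-bit range (see
#' [rescale_to_8bit()]) because `low_contrast_cut` is defined on that scale.
#'
#' @param img A [channel_image()].
#' @param params A [bernsen_params()].
#' @return A [binary_mask()] of the same dimensions as `img`.
#' @examples
#' img <- channel_image(matrix(200L, 8, 8), role = "PHA")
#' mask <- bernsen_threshold(img, bernsen_params())
#' all(mask$pixels)  # uniform bright field -> all object
#' @export
bernsen_threshold <- function(img, params = bernsen_params()) {
  stopifnot(inherits(img, "channel_image"), inherits(params, "bernsen_params"))
  img8 <- rescale_to_8bit(img)
  px <- bernsen_cpp(img8$pixels, params$radius, params$contrast_threshold,
                    params$low_contrast_cut)
  binary_mask(px, provenance = list(role = img$role, bit_depth = img$bit_depth,
                                    params = unclass(params)))
}
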