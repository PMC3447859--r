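#' RGB brightfield micrograph container
#'
#' An `rgb_field` holds an H x W x 3 array of intensities in `[0, 1]` together
#' with the physical pixel size (micrometers per pixel) and an identifier. It is
#' the raw input of the segmentation pipeline and the output of the synthetic
#' field generator.
#'
#' @param pixels numeric array of dimension `c(H, W, 3)` with values in `[0, 1]`.
#' @param pixel_size physical pixel size in micrometers per pixel.
#' @param field_id character identifier carried through per-field summaries.
#'
#' @return An object of class `rgb_field`.
#' @examples
#' f <- rgb_field(array(0.5, dim = c(64, 64, 3)), pixel_size = 0.5)
#' dim(f$pixels)
#' @export
rgb_field <- function(pixels, pixel_size = 1, field_id = "field") {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop_ihc("`pixels` must be an H x W x 3 array", "ihcquant_bad_input")
  }
  if (dim(pixels)[1] < 32 || dim(pixels)[2] < 32) {
    stop_ihc("image must be at least 32 x 32 pixels", "ihcquant_bad_input")
  }
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop_ihc("intensities must lie in [0, 1]", "ihcquant_bad_input")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop_ihc("`pixel_size` must be a positive scalar (um/px)", "ihcquant_bad_input")
  }
  structure(
    list(
      pixels = pixels,
      pixel_size = pixel_size,
      field_id = as.character(field_id)
    ),
    class = "rgb_field"
  )
}

#' @export
print.rgb_field <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<rgb_field '%s'> %d x %d px, %.3g um/px, intensity range [%.3f, %.3f]\n",
    x$field_id, d[1], d[2], x$pixel_size, min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.rgb_field <- function(x) dim(x$pixels)

is_rgb_field <- function(x) inherits(x, "rgb_field")

assert_rgb_field <- function(x, arg = "image") {
  if (!is_rgb_field(x)) {
    stop_ihc(sprintf("`%s` must be an rgb_field object", arg), "ihcquant_bad_input")
  }
  invisible(x)
}

# channel accessors -----------------------------------------------------------

channel <- function(field, i) field$pixels[, , i]

# Rebuild a field with new pixel data, keeping metadata.
with_pixels <- function(field, pixels) {
  field$pixels <- pixels
  field
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Dice overlap coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; used to score a segmentation against the
#' ground-truth mask of a synthetic field. Two empty masks have Dice 1.
#'
#' @param a,b logical matrices of identical dimension.
#' @return A number in `[0, 1]`.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
#' dice_coefficient(m, m)
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop_ihc("masks must have identical dimensions", "ihcquant_bad_input")
  }
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
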