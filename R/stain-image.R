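#' Stain image container
#'
#' A 2-D grayscale intensity grid with an attached pixel scale and a tag for
#' the source channel (amyloid stain, DAPI, T-cell marker, ...). The matrix is
#' stored with row index = y and column index = x; pixel (i, j) (1-based in R)
#' has its centre at x = (j - 1) * s, y = (i - 1) * s micrometres, where s is
#' the pixel size.
#'
#' @param intensity Numeric matrix of pixel intensities (any native range).
#' @param scale A [pixel_scale()].
#' @param channel Channel tag, one of "amyloid", "dapi", "tcell", "other".
#' @return An object of class `stain_image`.
#' @export
stain_image <- function(intensity, scale = pixel_scale(),
                        channel = c("amyloid", "dapi", "tcell", "other")) {
  channel <- match.arg(channel)
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    abort("`intensity` must be a numeric matrix.")
  }
  if (any(dim(intensity) == 0)) abort("zero-size image.")
  structure(
    list(intensity = intensity, scale = as_pixel_scale(scale), channel = channel),
    class = "stain_image"
  )
}

#' @export
print.stain_image <- function(x, ...) {
  cat(sprintf("<stain_image> %d x %d px (%g um/px), channel: %s\n",
              nrow(x$intensity), ncol(x$intensity),
              x$scale$microns_per_pixel, x$channel))
  invisible(x)
}

#' @export
dim.stain_image <- function(x) dim(x$intensity)

#' Min-max normalized view of an image
#'
#' Rescales intensities to `[0, 1]`. A constant image has no dynamic range;
#' its normalized view is all zeros and carries attribute `degenerate = TRUE`.
#'
#' @param img A [stain_image()] or numeric matrix.
#' @return Numeric matrix in `[0, 1]`.
#' @export
normalize_image <- function(img) {
  m <- if (inherits(img, "stain_image")) img$intensity else img
  rng <- range(m)
  if (rng[1] == rng[2]) {
    out <- matrix(0, nrow(m), ncol(m))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (m - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' Read a stain image from TIFF
#'
#' Multi-channel (3-D) TIFFs require an explicit `channel_index`. Integer data
#' are read back on their native scale.
#'
#' @param path Path to a TIFF file.
#' @param scale A [pixel_scale()].
#' @param channel Channel tag (see [stain_image()]).
#' @param channel_index For multi-channel TIFFs, which plane to take.
#' @return A [stain_image()].
#' @export
read_stain_image <- function(path, scale = pixel_scale(),
                             channel = c("amyloid", "dapi", "tcell", "other"),
                             channel_index = NULL) {
  channel <- match.arg(channel)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  m <- tiff::readTIFF(path, info = TRUE)
  bps <- attr(m, "bits.per.sample") %||% 8L
  if (bps[1] < 32) {
    # integer-sampled TIFF: recover native integer values
    m <- tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(m)) == 3) {
    if (is.null(channel_index)) {
      abort("multi-channel TIFF: supply `channel_index` to select a plane.")
    }
    if (channel_index < 1 || channel_index > dim(m)[3]) {
      abort(sprintf("`channel_index` %d out of range 1..%d",
                    channel_index, dim(m)[3]))
    }
    m <- m[, , channel_index]
  }
  if (!is.matrix(m)) abort("not a 2-D image.")
  if (any(dim(m) == 0)) abort("zero-size image.")
  attributes(m) <- list(dim = dim(m))
  stain_image(m * 1.0, scale = scale, channel = channel)
}

#' Write a stain image to TIFF
#'
#' Integer-valued images within 0..65535 are stored as 16-bit integer TIFF
#' (exact round trip); real-valued images in `[0, 1]` are stored as 32-bit
#' float. Other ranges must be rescaled by the caller first.
#'
#' @param img A [stain_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stain_image <- function(img, path) {
  stopifnot(inherits(img, "stain_image"))
  m <- img$intensity
  if (all(m == round(m)) && all(m >= 0) && all(m <= 65535)) {
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  } else if (all(m >= 0) && all(m <= 1)) {
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
  } else {
    abort("image values must be integers in 0..65535 or reals in [0, 1]; rescale before writing.")
  }
  invisible(path)
}
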