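#' Pixel scale of a rendered slide image
#'
#' Molecular Cartography exports render transcript coordinates and stain
#' images on a pixel grid; all analysis in this package is carried out in
#' micrometres. The default of 0.138 um/px follows from the platform's
#' rendered-image equivalence of 69 um to 500 px.
#'
#' @param microns_per_pixel Strictly positive length ratio (um/px).
#' @return An object of class `pixel_scale`.
#' @examples
#' s <- pixel_scale()            # 0.138 um/px
#' px_to_um(500, s)              # 69 um
#' @export
pixel_scale <- function(microns_per_pixel = 0.138) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    abort("`microns_per_pixel` must be a single finite number > 0.")
  }
  structure(list(microns_per_pixel = as.numeric(microns_per_pixel)),
            class = "pixel_scale")
}

as_pixel_scale <- function(scale) {
  if (inherits(scale, "pixel_scale")) return(scale)
  pixel_scale(scale)
}

#' @export
print.pixel_scale <- function(x, ...) {
  cat(sprintf("<pixel_scale> %g um/px\n", x$microns_per_pixel))
  invisible(x)
}

#' Convert pixel coordinates to micrometres and back
#'
#' @param px,um Numeric coordinates.
#' @param scale A [pixel_scale()] (or a bare um/px number).
#' @return Numeric vector of converted coordinates.
#' @export
px_to_um <- function(px, scale = pixel_scale()) {
  px * as_pixel_scale(scale)$microns_per_pixel
}

#' @rdname px_to_um
#' @export
um_to_px <- function(um, scale = pixel_scale()) {
  um / as_pixel_scale(scale)$microns_per_pixel
}
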