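#' Rolling-ball style background subtraction
#'
#' Estimates the slowly varying background as the grayscale morphological
#' opening of the image with a disc structuring element of the given radius
#' and subtracts it; output is nonnegative. A constant image maps to zero;
#' isolated bright objects smaller than the disc are preserved.
#'
#' @param img A [stain_image()].
#' @param radius Structuring-element radius, px (>= 1, smaller than the
#'   image).
#' @return A [stain_image()] on the same intensity scale.
#' @export
subtract_background <- function(img, radius = 30) {
  stopifnot(inherits(img, "stain_image"))
  if (radius < 1) abort("`radius` must be >= 1.")
  if (2 * radius + 1 >= min(dim(img$intensity))) {
    abort("`radius` too large for the image dimensions.")
  }
  m <- img$intensity
  # replicate edges so the structuring element never runs off the image
  # (otherwise the opening dips near borders and leaves bump artifacts)
  ri <- c(rep(1L, radius), seq_len(nrow(m)), rep(nrow(m), radius))
  ci <- c(rep(1L, radius), seq_len(ncol(m)), rep(ncol(m), radius))
  pad <- m[ri, ci]
  # EBImage grayscale morphology operates on [0, 1]
  top <- max(pad, 1)
  bg <- as.matrix(EBImage::opening(pad / top,
                                   EBImage::makeBrush(2 * radius + 1, "disc")))
  bg <- bg[radius + seq_len(nrow(m)), radius + seq_len(ncol(m))]
  out <- pmax(m - bg * top, 0)
  stain_image(out, scale = img$scale, channel = img$channel)
}

#' Detect nuclei as prominence-filtered intensity maxima
#'
#' Gaussian-smooths the (background-subtracted) DAPI channel and keeps local
#' maxima whose topographic prominence -- height above the highest saddle to
#' any higher maximum -- is at least `prominence`. Sub-peaks of a common
#' blob merge below the threshold; plateaus resolve deterministically to
#' their first pixel in raster order. The ImageJ tool this mirrors exposes a
#' blur "radius"; here it is the Gaussian sigma in px.
#'
#' @param img A [stain_image()] (run [subtract_background()] first).
#' @param blur_radius Gaussian sigma, px.
#' @param prominence Minimum prominence on the image's native intensity
#'   scale.
#' @param exclude_border Margin in px inside which maxima are discarded
#'   (Gaussian smoothing is unreliable there); default `2 * blur_radius`.
#' @return Tibble of nucleus points: `x`, `y` (um), `value` (smoothed
#'   intensity at the peak).
#' @export
detect_nuclei <- function(img, blur_radius = 5, prominence = 1,
                          exclude_border = 2 * blur_radius) {
  stopifnot(inherits(img, "stain_image"))
  sm <- as.matrix(EBImage::gblur(img$intensity, sigma = blur_radius))
  pk <- .find_maxima_prominence(sm, prominence)
  if (exclude_border > 0 && nrow(pk) > 0) {
    keep <- pk[, "row"] > exclude_border &
      pk[, "row"] <= nrow(sm) - exclude_border &
      pk[, "col"] > exclude_border &
      pk[, "col"] <= ncol(sm) - exclude_border
    pk <- pk[keep, , drop = FALSE]
  }
  s <- img$scale$microns_per_pixel
  tibble(x = (pk[, "col"] - 1) * s, y = (pk[, "row"] - 1) * s,
         value = pk[, "value"])
}

#' Count T cells among detected nuclei
#'
#' The T-cell channel is thresholded into a signal mask; every nucleus
#' point lying inside the mask (at its nearest pixel) is counted as a
#' T cell, all nucleus points as total cells. By default the threshold is
#' on the min-max-normalized `[0, 1]` scale (invariant to rescaling the
#' channel); with `normalize = FALSE` it is an absolute cutoff on the
#' native intensity scale, mirroring a per-image threshold calibrated by
#' the operator -- the right choice when a channel may carry no signal at
#' all, where any relative threshold is degenerate.
#'
#' @param nuclei Tibble from [detect_nuclei()] (`x`, `y` in um).
#' @param tcell_img A [stain_image()] of the T-cell marker channel
#'   (background-subtracted and blurred upstream as appropriate).
#' @param channel_threshold Threshold: in `[0, 1]` when `normalize = TRUE`,
#'   native intensity units otherwise.
#' @param normalize Threshold on the normalized (`TRUE`, default) or native
#'   scale.
#' @return An object of class `count_result`: points with `is_tcell` flags,
#'   totals and the normalized T-cell frequency.
#' @export
count_tcells <- function(nuclei, tcell_img, channel_threshold = 0.5,
                         normalize = TRUE) {
  stopifnot(inherits(tcell_img, "stain_image"))
  if (normalize && (channel_threshold < 0 || channel_threshold > 1)) {
    abort("`channel_threshold` must be in [0, 1].")
  }
  mask <- if (normalize) {
    normalize_image(tcell_img) >= channel_threshold
  } else {
    tcell_img$intensity >= channel_threshold
  }
  s <- tcell_img$scale$microns_per_pixel
  n <- nrow(nuclei)
  flag <- logical(n)
  if (n > 0) {
    col <- pmin(pmax(round(nuclei$x / s) + 1L, 1L), ncol(mask))
    row <- pmin(pmax(round(nuclei$y / s) + 1L, 1L), nrow(mask))
    flag <- mask[cbind(row, col)]
  }
  structure(list(
    points = dplyr::mutate(as_tibble(nuclei), is_tcell = flag),
    n_nuclei = n, n_tcells = sum(flag),
    frequency = if (n > 0) sum(flag) / n else NA_real_,
    parameters = list(channel_threshold = channel_threshold,
                      normalize = normalize)
  ), class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d nuclei, %d T cells (frequency %.3f)\n",
              x$n_nuclei, x$n_tcells, x$frequency))
  invisible(x)
}

#' Per-plaque T-cell counts within a fixed radius
#'
#' Each flagged T cell is assigned to its nearest plaque centre if that
#' centre lies within `radius` pixels; assignment to the nearest centre
#' only prevents double counting when circles overlap.
#'
#' @param plaque_centers Data frame with `x`, `y` (um); e.g. plaque
#'   centroids from [segment_plaques()] or a manual list.
#' @param counts A `count_result` from [count_tcells()] (or a tibble with
#'   `x`, `y`, `is_tcell`).
#' @param radius Counting radius in px (default 90).
#' @param scale A [pixel_scale()] converting the radius to um.
#' @return Tibble `(plaque_id, n_tcells)` with a `mean_per_plaque`
#'   attribute.
#' @export
tcells_per_plaque <- function(plaque_centers, counts, radius = 90,
                              scale = pixel_scale()) {
  if (nrow(plaque_centers) == 0) abort("empty plaque centre list.")
  if (radius <= 0) abort("`radius` must be > 0.")
  pts <- if (inherits(counts, "count_result")) counts$points else as_tibble(counts)
  tc <- dplyr::filter(pts, .data$is_tcell)
  radius_um <- px_to_um(radius, scale)
  n_pl <- nrow(plaque_centers)
  assigned <- integer(n_pl)
  if (nrow(tc) > 0) {
    d <- sqrt(outer(tc$x, plaque_centers$x, "-")^2 +
                outer(tc$y, plaque_centers$y, "-")^2)
    nearest <- max.col(-d, ties.method = "first")
    ok <- d[cbind(seq_len(nrow(tc)), nearest)] <= radius_um
    assigned <- tabulate(nearest[ok], nbins = n_pl)
  }
  out <- tibble(plaque_id = seq_len(n_pl), n_tcells = assigned)
  attr(out, "mean_per_plaque") <- mean(assigned)
  out
}
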