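#' Segment amyloid plaques from a stain image
#'
#' Min-max normalizes the image, applies a global threshold (Otsu by default,
#' or a fixed value on the normalized `[0, 1]` scale), labels 8-connected
#' components in raster order of their first pixel, and removes components
#' smaller than `min_area`. Components touching the image border are kept but
#' flagged, since their surrounding zones are truncated by the field of view.
#'
#' @param img A [stain_image()] of the amyloid channel.
#' @param method Threshold method, `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold in `[0, 1]` when `method = "fixed"`.
#' @param min_area Minimum component area, um^2.
#' @return A `plaque_field`: label mask, per-plaque table (id, area_um2,
#'   centroid, border flag) and pixel scale. Use [distance_field()] to add
#'   the distance-to-nearest-plaque grid.
#' @export
segment_plaques <- function(img, method = c("otsu", "fixed"),
                            fixed_threshold = NULL, min_area = 10) {
  method <- match.arg(method)
  stopifnot(inherits(img, "stain_image"))
  norm <- normalize_image(img)
  if (method == "otsu") {
    if (isTRUE(attr(norm, "degenerate"))) {
      abort("constant image: Otsu threshold is degenerate; use method = 'fixed'.")
    }
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    if (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 1) {
      abort("`fixed_threshold` in [0, 1] is required for method = 'fixed'.")
    }
    thr <- fixed_threshold
  }
  mask <- norm > thr
  field <- plaque_field_from_mask(mask, img$scale, min_area = min_area)
  field$threshold <- thr
  if (nrow(field$plaques) == 0) {
    warn("no plaque component survived thresholding and the area filter.")
  }
  field
}

#' Build a plaque field directly from a binary or labeled mask
#'
#' Bypasses thresholding: any nonzero pixel is plaque. Components are
#' relabeled 8-connected in raster order; an optional area filter applies.
#' Useful for ground-truth masks and for re-segmenting a binarized mask
#' (segmentation is idempotent under this construction).
#'
#' @param mask Logical/integer matrix.
#' @param scale A [pixel_scale()].
#' @param min_area Minimum component area, um^2.
#' @return A `plaque_field` (distance grid not yet built).
#' @export
plaque_field_from_mask <- function(mask, scale = pixel_scale(1), min_area = 0) {
  scale <- as_pixel_scale(scale)
  s <- scale$microns_per_pixel
  labels <- .label_components_8(matrix(as.logical(mask > 0), nrow(mask), ncol(mask)))
  pixel_area <- s^2
  k <- max(labels)
  if (k > 0 && min_area > 0) {
    areas <- tabulate(labels[labels > 0], nbins = k) * pixel_area
    drop <- which(areas < min_area)
    if (length(drop) > 0) {
      labels[labels %in% drop] <- 0L
      # renumber survivors; raster order of first pixel is preserved
      keep <- sort(setdiff(seq_len(k), drop))
      relab <- integer(k)
      relab[keep] <- seq_along(keep)
      pos <- labels > 0
      labels[pos] <- relab[labels[pos]]
    }
  }
  k <- max(labels)
  plaques <- if (k == 0) {
    tibble(plaque_id = integer(), area_um2 = numeric(),
           centroid_x = numeric(), centroid_y = numeric(), border = logical())
  } else {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    cx <- tapply(px_to_um(idx[, 2] - 1, scale), lab, mean)
    cy <- tapply(px_to_um(idx[, 1] - 1, scale), lab, mean)
    on_border <- idx[, 1] == 1 | idx[, 1] == nrow(labels) |
      idx[, 2] == 1 | idx[, 2] == ncol(labels)
    tibble(
      plaque_id = seq_len(k),
      area_um2 = as.numeric(tabulate(lab, nbins = k)) * pixel_area,
      centroid_x = as.numeric(cx),
      centroid_y = as.numeric(cy),
      border = as.logical(tapply(on_border, lab, any))
    )
  }
  structure(list(labels = labels, distance = NULL, nearest = NULL,
                 scale = scale, plaques = plaques),
            class = "plaque_field")
}

#' @export
print.plaque_field <- function(x, ...) {
  cat(sprintf("<plaque_field> %d x %d px (%g um/px), %d plaque(s)%s\n",
              nrow(x$labels), ncol(x$labels), x$scale$microns_per_pixel,
              nrow(x$plaques),
              if (is.null(x$distance)) ", distance not built" else ""))
  invisible(x)
}

#' Euclidean distance-to-nearest-plaque field
#'
#' Fills the `distance` grid (um) of a `plaque_field` with the exact Euclidean
#' distance transform of the background relative to the labeled plaque set
#' (0 on plaque pixels), plus a `nearest` grid holding the id of the closest
#' plaque (ties broken by lower id). With no plaques all distances are `Inf`.
#'
#' @param field A `plaque_field` from [segment_plaques()] or
#'   [plaque_field_from_mask()].
#' @return The field with `distance` and `nearest` grids filled.
#' @export
distance_field <- function(field) {
  stopifnot(inherits(field, "plaque_field"))
  labels <- field$labels
  s <- field$scale$microns_per_pixel
  k <- nrow(field$plaques)
  if (k == 0) {
    field$distance <- matrix(Inf, nrow(labels), ncol(labels))
    field$nearest <- matrix(0L, nrow(labels), ncol(labels))
    return(field)
  }
  best <- matrix(Inf, nrow(labels), ncol(labels))
  nearest <- matrix(0L, nrow(labels), ncol(labels))
  for (id in seq_len(k)) {
    d <- as.matrix(EBImage::distmap(1 - (labels == id))) * s
    upd <- d < best
    best[upd] <- d[upd]
    nearest[upd] <- id
  }
  field$distance <- best
  field$nearest <- nearest
  field
}

#' Distance of points to the nearest plaque
#'
#' Looks up the distance field at the pixel whose centre is nearest to each
#' (continuous) point. Out-of-bounds points get `in_bounds = FALSE` and `NA`
#' distance.
#'
#' @param field A `plaque_field` with the distance grid built (it is built on
#'   the fly otherwise).
#' @param points Data frame with `x`, `y` in um.
#' @return The input tibble with `distance` (um), `nearest_plaque_id` and
#'   `in_bounds` columns appended, row order preserved.
#' @export
query_distance <- function(field, points) {
  stopifnot(inherits(field, "plaque_field"))
  if (is.null(field$distance)) field <- distance_field(field)
  points <- as_tibble(points)
  n <- nrow(points)
  if (n == 0) {
    return(dplyr::mutate(points, distance = numeric(0),
                         nearest_plaque_id = integer(0), in_bounds = logical(0)))
  }
  s <- field$scale$microns_per_pixel
  col <- round(points$x / s) + 1L
  row <- round(points$y / s) + 1L
  ok <- row >= 1L & row <= nrow(field$labels) & col >= 1L & col <= ncol(field$labels)
  d <- rep(NA_real_, n)
  np <- rep(NA_integer_, n)
  idx <- cbind(row[ok], col[ok])
  d[ok] <- field$distance[idx]
  np[ok] <- field$nearest[idx]
  np[!is.na(np) & np == 0L] <- NA_integer_
  dplyr::mutate(points, distance = d, nearest_plaque_id = np, in_bounds = ok)
}
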