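#' Plot an annulus-renormalized distance profile
#'
#' @param object A `distance_profile` from [distance_profile()] or
#'   [marker_set_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance (µm)",
                  y = "annulus-normalized density (µm⁻²)") +
    ggplot2::theme_minimal()
}

#' Plot zone densities per gene
#'
#' Per-plaque tables give one point per plaque; global tables one bar per
#' zone.
#'
#' @param object A `zone_density` table from [zone_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zone_density <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$zone, y = .data$density))
  p <- if ("plaque_id" %in% names(df)) {
    p + ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5)
  } else {
    p + ggplot2::geom_col()
  }
  p + ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "transcript density (µm⁻²)") +
    ggplot2::theme_minimal()
}

#' Plot a plaque field
#'
#' Distance-to-nearest-plaque raster with plaque pixels overlaid.
#'
#' @param object A `plaque_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plaque_field <- function(object, ...) {
  if (is.null(object$distance)) object <- distance_field(object)
  s <- object$scale$microns_per_pixel
  df <- tibble(
    x = as.vector((col(object$distance) - 1) * s),
    y = as.vector((row(object$distance) - 1) * s),
    distance = as.vector(object$distance),
    plaque = as.vector(object$labels) > 0
  )
  df$distance[!is.finite(df$distance)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$distance)) +
    ggplot2::geom_raster(data = df[df$plaque, ], fill = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  fill = "d to plaque (µm)") +
    ggplot2::theme_minimal()
}

#' Plot counted nuclei and T cells
#'
#' @param object A `count_result` from [count_tcells()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.count_result <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$x, .data$y, colour = .data$is_tcell)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "T cell",
                  subtitle = sprintf("%d nuclei, %d T cells",
                                     object$n_nuclei, object$n_tcells)) +
    ggplot2::theme_minimal()
}

#' Plot a Spearman correlation with its linear fit
#'
#' @param object A `spearman_fit` from [correlate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spearman_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
    ggplot2::labs(subtitle = sprintf("Spearman rho = %.2f, p = %.3g",
                                     object$rho, object$p_value)) +
    ggplot2::theme_minimal()
}
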