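#' Assign points to plaque-proximity zones
#'
#' The tissue is partitioned by distance d to the nearest plaque into three
#' zones: inside (d = 0, i.e. on a plaque pixel), plaque-adjacent
#' (0 < d <= `zone_radius`) and outside (d > `zone_radius`). The upper zone
#' boundary is closed: a point exactly at `zone_radius` is adjacent.
#'
#' @param field A `plaque_field` (distance grid built on the fly if absent).
#' @param points Data frame with `x`, `y` in um (extra columns preserved).
#' @param zone_radius Adjacent-zone width, um (default 69).
#' @return Tibble: input columns plus `distance`, `nearest_plaque_id`,
#'   `in_bounds` and `zone` (factor inside/adjacent/outside; `NA` for
#'   out-of-bounds points).
#' @export
assign_zones <- function(field, points, zone_radius = 69) {
  if (zone_radius <= 0) abort("`zone_radius` must be > 0.")
  if (nrow(field$plaques) == 0) {
    warn("no plaques in field: all in-bounds points are 'outside'.")
  }
  out <- query_distance(field, points)
  zone <- dplyr::case_when(
    !out$in_bounds ~ NA_character_,
    out$distance == 0 ~ "inside",
    out$distance <= zone_radius ~ "adjacent",
    TRUE ~ "outside"
  )
  out$zone <- factor(zone, levels = c("inside", "adjacent", "outside"))
  out
}

#' Pixel-counting zone areas
#'
#' Areas (um^2) of the three zones clipped to the imaged window; they
#' partition the window exactly. The per-plaque variant splits every zone by
#' the nearest plaque id (ties to the lower id), so per-plaque areas also sum
#' to the window area.
#'
#' @param field A `plaque_field`.
#' @param zone_radius Adjacent-zone width, um.
#' @param per_plaque Split areas by nearest plaque?
#' @return Tibble `(zone, area_um2)`, or `(plaque_id, zone, area_um2)` when
#'   `per_plaque = TRUE`.
#' @export
zone_areas <- function(field, zone_radius = 69, per_plaque = FALSE) {
  stopifnot(inherits(field, "plaque_field"))
  if (is.null(field$distance)) field <- distance_field(field)
  s <- field$scale$microns_per_pixel
  pixel_area <- s^2
  d <- field$distance
  zone <- ifelse(d == 0, "inside", ifelse(d <= zone_radius, "adjacent", "outside"))
  lv <- c("inside", "adjacent", "outside")
  if (!per_plaque) {
    n <- table(factor(zone, levels = lv))
    return(tibble(zone = factor(lv, levels = lv),
                  area_um2 = as.numeric(n) * pixel_area))
  }
  if (nrow(field$plaques) == 0) {
    return(tibble(plaque_id = integer(), zone = factor(character(), levels = lv),
                  area_um2 = numeric()))
  }
  tab <- table(factor(field$nearest, levels = seq_len(nrow(field$plaques))),
               factor(zone, levels = lv))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("plaque_id", "zone", "n")
  tibble(
    plaque_id = as.integer(out$plaque_id),
    zone = factor(out$zone, levels = lv),
    area_um2 = out$n * pixel_area
  ) |>
    dplyr::arrange(.data$plaque_id, .data$zone)
}

#' Area-normalized transcript density per zone
#'
#' Counts transcripts per gene and zone and divides by the zone area
#' (um^2), globally or per plaque. Zones with zero area get `NA` density
#' and are flagged.
#'
#' @param assignment Output of [assign_zones()] with a `gene` column.
#' @param areas Output of [zone_areas()] computed from the same field, with
#'   matching `per_plaque`.
#' @param genes Optional gene subset; genes absent from the data yield
#'   zero-count rows with a warning.
#' @param per_plaque Per-plaque densities (nearest-plaque partition)?
#' @param scale_genes Append `scaled_density`, the per-gene z-score of
#'   density across rows (display aid for cross-gene comparison).
#' @return A tibble of class `zone_density` with columns `gene`, `zone`
#'   (and `plaque_id` when per-plaque), `transcript_count`, `zone_area_um2`,
#'   `density` (count / um^2) and `area_defined`.
#' @export
zone_density <- function(assignment, areas, genes = NULL, per_plaque = FALSE,
                         scale_genes = FALSE) {
  stopifnot(all(c("gene", "zone") %in% names(assignment)))
  if (per_plaque && !"plaque_id" %in% names(areas)) {
    abort("`areas` must be per-plaque (zone_areas(..., per_plaque = TRUE)).")
  }
  pts <- dplyr::filter(assignment, .data$in_bounds)
  if (!is.null(genes)) {
    missing <- setdiff(genes, unique(pts$gene))
    if (length(missing) > 0) {
      warn(sprintf("gene(s) absent from the transcript table: %s",
                   paste(missing, collapse = ", ")))
    }
    pts <- dplyr::filter(pts, .data$gene %in% genes)
    gene_levels <- genes
  } else {
    gene_levels <- sort(unique(pts$gene))
  }
  lv <- c("inside", "adjacent", "outside")
  if (per_plaque) {
    # outside points keep their nearest plaque id as well
    counts <- pts |>
      dplyr::count(gene = factor(.data$gene, levels = gene_levels),
                   plaque_id = .data$nearest_plaque_id, .data$zone,
                   name = "transcript_count", .drop = FALSE) |>
      dplyr::filter(!is.na(.data$plaque_id))
    grid <- tidyr::expand_grid(gene = gene_levels,
                               areas[, c("plaque_id", "zone", "area_um2")])
    out <- dplyr::left_join(grid,
                            dplyr::mutate(counts, gene = as.character(.data$gene)),
                            by = c("gene", "plaque_id", "zone"))
  } else {
    counts <- pts |>
      dplyr::count(gene = factor(.data$gene, levels = gene_levels), .data$zone,
                   name = "transcript_count", .drop = FALSE)
    grid <- tidyr::expand_grid(gene = gene_levels,
                               areas[, c("zone", "area_um2")])
    out <- dplyr::left_join(grid,
                            dplyr::mutate(counts, gene = as.character(.data$gene)),
                            by = c("gene", "zone"))
  }
  out <- out |>
    dplyr::mutate(
      transcript_count = dplyr::coalesce(.data$transcript_count, 0L),
      zone_area_um2 = .data$area_um2,
      area_defined = .data$area_um2 > 0,
      density = ifelse(.data$area_defined,
                       .data$transcript_count / .data$area_um2, NA_real_)
    ) |>
    dplyr::select(-"area_um2")
  if (scale_genes) {
    out <- out |>
      dplyr::group_by(.data$gene) |>
      dplyr::mutate(scaled_density = {
        m <- mean(.data$density, na.rm = TRUE)
        s <- sd(.data$density, na.rm = TRUE)
        if (is.na(s) || s == 0) .data$density * 0 else (.data$density - m) / s
      }) |>
      dplyr::ungroup()
  }
  structure(out, class = c("zone_density", "tbl_df", "tbl", "data.frame"))
}
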