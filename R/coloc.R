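#' Annulus areas of distance-histogram bins
#'
#' Bin b of width w covers distances `[(b-1)w, bw)`; the area of the
#' corresponding ring is pi * w^2 * (2b - 1) = pi * ((bw)^2 - ((b-1)w)^2).
#' Dividing per-bin counts by these areas converts a distance histogram into
#' a radially comparable density.
#'
#' @param n_bins Number of bins.
#' @param bin_width Bin width, um.
#' @return Numeric vector of ring areas (um^2).
#' @export
annulus_areas <- function(n_bins, bin_width) {
  b <- seq_len(n_bins)
  pi * bin_width^2 * (2 * b - 1)
}

new_distance_profile <- function(df, n_reference, bin_width, max_range) {
  structure(df, class = c("distance_profile", "tbl_df", "tbl", "data.frame"),
            n_reference = n_reference, bin_width = bin_width,
            max_range = max_range)
}

# Histogram of distances from each reference point to all marker points,
# averaged over references. Returns counts summed over references plus the
# per-reference mean.
pair_histogram <- function(mx, my, rx, ry, bin_width, max_range) {
  n_bins <- max_range / bin_width
  total <- numeric(n_bins)
  # chunk references to bound the nref x nmark distance block
  chunk <- max(1L, floor(5e6 / max(1L, length(mx))))
  for (start in seq(1L, length(rx), by = chunk)) {
    ii <- start:min(start + chunk - 1L, length(rx))
    d <- sqrt(outer(rx[ii], mx, "-")^2 + outer(ry[ii], my, "-")^2)
    bin <- floor(d / bin_width) + 1
    bin <- bin[bin >= 1 & bin <= n_bins]
    total <- total + tabulate(bin, nbins = n_bins)
  }
  total
}

#' Annulus-renormalized distance profile between two point sets
#'
#' For each reference ("marker 2") point, the histogram of its distances to
#' all marker-1 points is computed with equal-width bins; histograms are
#' averaged over reference points and each bin is divided by its ring area
#' ([annulus_areas()]). Under complete spatial randomness of marker 1 with
#' intensity lambda the profile is flat at lambda. Optionally the reference
#' points are restricted to the plaque-inside + adjacent zones of a field.
#'
#' @param marker_points Data frame with `x`, `y` (um): the marker-1 points.
#' @param reference_points Data frame with `x`, `y` (um): the reference
#'   (marker-2) points over which histograms are averaged.
#' @param bin_width Bin width, um.
#' @param max_range Histogram range, um; must be a multiple of `bin_width`.
#' @param restrict_zones Optional character vector of zones (e.g.
#'   `c("inside", "adjacent")`): reference points outside these zones are
#'   dropped. Requires `field`.
#' @param field,zone_radius Plaque field and zone radius for the restriction.
#' @return A `distance_profile` tibble: `bin`, `bin_lo`, `bin_hi`,
#'   `raw_count` (pairs in bin), `mean_count` (per reference),
#'   `annulus_area`, `density` (= mean_count / annulus_area).
#' @export
distance_profile <- function(marker_points, reference_points,
                             bin_width = 5, max_range = 200,
                             restrict_zones = NULL, field = NULL,
                             zone_radius = 69) {
  if (bin_width <= 0) abort("`bin_width` must be > 0.")
  n_bins <- max_range / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8) {
    abort("`max_range` must be a multiple of `bin_width`.")
  }
  n_bins <- as.integer(round(n_bins))
  refs <- as_tibble(reference_points)
  if (!is.null(restrict_zones)) {
    if (is.null(field)) abort("`field` is required with `restrict_zones`.")
    za <- assign_zones(field, refs, zone_radius = zone_radius)
    refs <- refs[!is.na(za$zone) & za$zone %in% restrict_zones, , drop = FALSE]
  }
  if (nrow(refs) == 0) abort("empty reference point set.")
  marks <- as_tibble(marker_points)
  areas <- annulus_areas(n_bins, bin_width)
  if (nrow(marks) == 0) {
    warn("empty marker-1 point set: all-zero profile.")
    total <- numeric(n_bins)
  } else {
    total <- pair_histogram(marks$x, marks$y, refs$x, refs$y,
                            bin_width, max_range)
  }
  mean_count <- total / nrow(refs)
  new_distance_profile(
    tibble(
      bin = seq_len(n_bins),
      bin_lo = (seq_len(n_bins) - 1) * bin_width,
      bin_hi = seq_len(n_bins) * bin_width,
      raw_count = total,
      mean_count = mean_count,
      annulus_area = areas,
      density = mean_count / areas
    ),
    n_reference = nrow(refs), bin_width = bin_width, max_range = max_range
  )
}

#' Mean colocalization profile of a gene set
#'
#' Computes a [distance_profile()] for each gene of a set (as marker 1)
#' against the reference gene's transcripts and averages the profiles
#' bin-wise. Set genes absent from the table are dropped with a warning.
#'
#' @param transcripts Tibble with `x`, `y`, `gene`.
#' @param set_genes Character vector: the marker set.
#' @param reference_gene Single gene whose transcripts act as references.
#' @param ... Passed to [distance_profile()] (`bin_width`, `max_range`,
#'   `restrict_zones`, `field`, `zone_radius`).
#' @return A `distance_profile` with the bin-wise mean `density` (and mean
#'   counts) over the set, plus a `n_genes` attribute.
#' @export
marker_set_profile <- function(transcripts, set_genes, reference_gene, ...) {
  present <- intersect(set_genes, unique(transcripts$gene))
  absent <- setdiff(set_genes, present)
  if (length(absent) > 0) {
    warn(sprintf("set gene(s) absent from the table: %s",
                 paste(absent, collapse = ", ")))
  }
  if (length(present) == 0) abort("no set gene present in the table.")
  refs <- dplyr::filter(transcripts, .data$gene == reference_gene)
  profiles <- purrr::map(present, function(g) {
    distance_profile(dplyr::filter(transcripts, .data$gene == g), refs, ...)
  })
  out <- profiles[[1]]
  for (col in c("raw_count", "mean_count", "density")) {
    out[[col]] <- rowMeans(vapply(profiles, function(p) p[[col]],
                                  numeric(nrow(out))))
  }
  attr(out, "n_genes") <- length(present)
  out
}

#' Relative overrepresentation of a gene around plaques
#'
#' Probability-density histograms (area one before ring correction) of
#' transcript distance-to-plaque for one gene and for all panel genes
#' pooled, both renormalized by the ring areas, and their per-bin ratio.
#' A ratio above 1 marks distances at which the gene is overrepresented
#' relative to the panel-wide baseline. Units of the renormalized
#' histograms are relative (probability density per ring area), not
#' absolute intensity.
#'
#' @param transcripts Tibble with `x`, `y`, `gene` (the full panel table;
#'   it is its own baseline).
#' @param gene Gene to profile.
#' @param field A `plaque_field` (reference = plaque boundary via the
#'   distance grid).
#' @param bin_width,max_range Histogram geometry, um.
#' @return Tibble of class `overrep_profile`: `bin`, `bin_lo`, `bin_hi`,
#'   `annulus_area`, `gene_density`, `baseline_density`, `ratio`; attributes
#'   `n_gene`, `n_baseline`, `low_count` (fewer than 10 transcripts).
#' @export
relative_overrepresentation <- function(transcripts, gene, field,
                                        bin_width = 5, max_range = 200) {
  n_bins <- max_range / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8) {
    abort("`max_range` must be a multiple of `bin_width`.")
  }
  n_bins <- as.integer(round(n_bins))
  all_d <- query_distance(field, transcripts)
  all_d <- dplyr::filter(all_d, .data$in_bounds, is.finite(.data$distance))
  gene_d <- dplyr::filter(all_d, .data$gene == !!gene)
  low_count <- nrow(gene_d) < 10
  if (low_count) {
    warn(sprintf("gene '%s' has %d transcript(s) (< 10): low-count profile.",
                 gene, nrow(gene_d)))
  }
  areas <- annulus_areas(n_bins, bin_width)
  dens_hist <- function(d) {
    bin <- floor(d / bin_width) + 1
    bin <- bin[bin >= 1 & bin <= n_bins]
    if (length(bin) == 0) return(rep(NaN, n_bins))
    # probability density over the histogram range, then ring renormalization
    (tabulate(bin, nbins = n_bins) / (length(bin) * bin_width)) / areas
  }
  gd <- dens_hist(gene_d$distance)
  bd <- dens_hist(all_d$distance)
  structure(
    tibble(
      bin = seq_len(n_bins),
      bin_lo = (seq_len(n_bins) - 1) * bin_width,
      bin_hi = seq_len(n_bins) * bin_width,
      annulus_area = areas,
      gene_density = gd,
      baseline_density = bd,
      ratio = gd / bd
    ),
    class = c("overrep_profile", "tbl_df", "tbl", "data.frame"),
    n_gene = nrow(gene_d), n_baseline = nrow(all_d), low_count = low_count,
    bin_width = bin_width, max_range = max_range
  )
}
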