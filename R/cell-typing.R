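#' Marker-missingness and minimum-count filtering
#'
#' The marker panel varies across samples, so some cell x gene entries are
#' unmeasured (missing, `NA`) rather than zero. Genes with `>=
#' max_missing_per_gene` missing entries are removed; the remaining missing
#' values are then imputed to 0; finally cells with fewer than
#' `min_counts_per_cell` total counts are removed (a cell at exactly the
#' minimum is kept).
#'
#' @param cm A [cell_matrix()].
#' @param max_missing_per_gene Genes with at least this many missing entries
#'   are dropped (default 60000, matching the full-scale dataset).
#' @param min_counts_per_cell Minimum total counts for a cell to be kept.
#' @return A filtered [cell_matrix()] without missing values, with a
#'   `filter_report` attribute (genes/cells kept and dropped).
#' @export
filter_matrix <- function(cm, max_missing_per_gene = 60000,
                          min_counts_per_cell = 20) {
  stopifnot(inherits(cm, "cell_matrix"))
  counts <- cm$counts
  n_missing <- colSums(is.na(counts))
  keep_gene <- n_missing < max_missing_per_gene
  if (!any(keep_gene)) {
    abort(sprintf("no gene has fewer than %d missing values.",
                  max_missing_per_gene))
  }
  counts <- counts[, keep_gene, drop = FALSE]
  counts[is.na(counts)] <- 0
  totals <- rowSums(counts)
  keep_cell <- totals >= min_counts_per_cell
  if (!any(keep_cell)) {
    abort(sprintf("no cell reaches %d total counts.", min_counts_per_cell))
  }
  report <- list(
    genes_in = ncol(cm$counts), genes_kept = sum(keep_gene),
    genes_dropped = sum(!keep_gene),
    cells_in = nrow(cm$counts), cells_kept = sum(keep_cell),
    cells_dropped = sum(!keep_cell)
  )
  inform(sprintf(
    "filter_matrix: kept %d/%d genes (missingness) and %d/%d cells (min counts)",
    report$genes_kept, report$genes_in, report$cells_kept, report$cells_in))
  out <- cell_matrix(counts[keep_cell, , drop = FALSE],
                     cm$cells[keep_cell, , drop = FALSE])
  attr(out, "filter_report") <- report
  out
}

#' Analytic Pearson-residual normalization
#'
#' Normalizes a cell x gene count matrix with analytic Pearson residuals
#' under a count model with expectation `mu_ij = rowsum_i * colsum_j / total`
#' and negative-binomial variance `mu + mu^2 / theta`:
#' `r_ij = (x_ij - mu_ij) / sqrt(mu_ij + mu_ij^2 / theta)`, clipped to
#' `+/- sqrt(n_cells)`. `theta -> Inf` recovers Poisson residuals.
#'
#' @param counts Nonnegative integer matrix (cells x genes), or a
#'   [cell_matrix()] without missing values.
#' @param theta Overdispersion parameter (default 100).
#' @param clip Clip bound; default `sqrt(n_cells)`.
#' @return Residual matrix with attributes `theta` and `clip_bound`, class
#'   `pearson_residuals`.
#' @export
pearson_residuals <- function(counts, theta = 100, clip = NULL) {
  if (inherits(counts, "cell_matrix")) counts <- counts$counts
  if (anyNA(counts)) abort("missing values present: run filter_matrix() first.")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be nonnegative integers.")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("need at least 2 cells and 2 genes.")
  }
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    bad_r <- rownames(counts)[rs == 0] %||% which(rs == 0)
    bad_c <- colnames(counts)[cs == 0] %||% which(cs == 0)
    abort(sprintf(
      "all-zero row(s)/column(s), expectation undefined: cells [%s], genes [%s]",
      paste(head(bad_r, 5), collapse = ", "),
      paste(head(bad_c, 5), collapse = ", ")))
  }
  total <- sum(counts)
  mu <- outer(rs, cs) / total
  r <- (counts - mu) / sqrt(mu + mu^2 / theta)
  bound <- clip %||% sqrt(nrow(counts))
  r[r > bound] <- bound
  r[r < -bound] <- -bound
  structure(r, theta = theta, clip_bound = bound,
            class = c("pearson_residuals", "matrix", "array"))
}

#' PCA + graph-based clustering of normalized cells
#'
#' Centers the residual matrix, takes the leading principal components,
#' builds a k-nearest-neighbour graph in PC space and partitions it with
#' Leiden community detection (modularity objective, fixed seed).
#'
#' @param norm Residual matrix from [pearson_residuals()] (cells x genes).
#' @param n_pcs Number of principal components (capped at dims - 1).
#' @param k Neighbours per cell for the kNN graph.
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed for the community detection.
#' @return Integer cluster labels (1-based), aligned with rows of `norm`.
#' @export
reduce_and_cluster <- function(norm, n_pcs = 20, k = 30, resolution = 0.5,
                               seed = 1) {
  norm <- unclass(norm)
  n <- nrow(norm)
  if (n <= k) abort(sprintf("fewer cells (%d) than kNN neighbours + 1 (%d).",
                            n, k + 1))
  n_pcs <- min(n_pcs, n - 1, ncol(norm))
  pcs <- prcomp(norm, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  dmat <- as.matrix(stats::dist(pcs))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(dmat[i, ])[2:(k + 1)]
    cbind(i, nb)
  }))
  edges <- unique(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = resolution,
      n_iterations = 10))
  })
  as.integer(memb)
}

#' Expression-bin-matched gene-set score
#'
#' Per-cell score of a gene set: mean expression of the set genes minus the
#' mean expression of an expression-matched control pool. For every set
#' gene, one control gene is drawn (seeded) from the non-set genes nearest
#' to it in mean expression (a window of panel-size / `n_bins` genes, at
#' least 4); when the set is the whole panel the controls are the set
#' itself and the score is exactly zero.
#'
#' @param expr Numeric matrix cells x genes (normalized expression or
#'   residuals).
#' @param set_genes Character vector; genes absent from `expr` are dropped
#'   with a warning.
#' @param n_bins Number of expression bins (default 25).
#' @param seed RNG seed for control sampling.
#' @return Numeric per-cell score vector.
#' @export
score_gene_set <- function(expr, set_genes, n_bins = 25, seed = 1) {
  if (inherits(expr, "pearson_residuals")) expr <- unclass(expr)
  if (is.null(colnames(expr))) abort("`expr` must have gene column names.")
  present <- intersect(set_genes, colnames(expr))
  absent <- setdiff(set_genes, present)
  if (length(absent) > 0) {
    warn(sprintf("set gene(s) absent from the panel: %s",
                 paste(absent, collapse = ", ")))
  }
  if (length(present) == 0) abort("no set gene present in the panel.")
  gene_means <- colMeans(expr)
  rk <- rank(gene_means, ties.method = "first")
  names(rk) <- colnames(expr)
  nonset <- setdiff(colnames(expr), present)
  window <- max(4L, ceiling(ncol(expr) / n_bins))
  ctrl <- if (length(nonset) == 0) {
    present
  } else {
    with_seed(seed, {
      unique(unlist(lapply(present, function(gn) {
        cand <- nonset[order(abs(rk[nonset] - rk[gn]))]
        sample(head(cand, window), 1)
      })))
    })
  }
  set_mean <- rowMeans(expr[, present, drop = FALSE])
  ctrl_mean <- rowMeans(expr[, ctrl, drop = FALSE])
  as.numeric(set_mean - ctrl_mean)
}

#' Annotate clusters by gene-set score separation
#'
#' For every cluster lc and candidate type ct, the separation score is
#' `s = (mean(score_ct over lc) - mean(score_ct over other cells)) /
#' (sd(score_ct over lc) + sd(score_ct over other cells))` with population
#' standard deviations. A cluster is assigned the type with the largest s
#' among those exceeding 1, or "unannotated" if none qualifies; multiple
#' qualifying types are reported. s is invariant to shifting all scores by a
#' constant or scaling by a positive factor.
#'
#' @param scores Data frame or matrix, cells x candidate types (named
#'   columns of per-cell scores from [score_gene_set()]).
#' @param clusters Cluster labels aligned with rows of `scores`.
#' @return An object of class `cluster_annotation` with a per-(cluster,
#'   type) score table and the per-cluster assignment; see `tidy()`.
#' @export
annotate_clusters <- function(scores, clusters) {
  scores <- as.data.frame(scores)
  if (nrow(scores) != length(clusters)) {
    abort("`scores` rows and `clusters` length differ.")
  }
  cl <- factor(clusters)
  if (nlevels(cl) == 1 && all(clusters == clusters[1])) {
    abort("a single cluster spans the whole dataset: no 'other cells' pool.")
  }
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  table <- tidyr::expand_grid(cluster = levels(cl), type = names(scores)) |>
    dplyr::rowwise() |>
    dplyr::mutate(separation = {
      v <- scores[[.data$type]]
      inside <- cl == .data$cluster
      num <- mean(v[inside]) - mean(v[!inside])
      den <- sd_pop(v[inside]) + sd_pop(v[!inside])
      if (den == 0) {
        if (num == 0) 0 else sign(num) * Inf
      } else num / den
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(qualifies = .data$separation > 1)
  assignment <- table |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      assigned_type = if (any(.data$qualifies)) {
        .data$type[which.max(ifelse(.data$qualifies, .data$separation, -Inf))]
      } else "unannotated",
      n_qualifying = sum(.data$qualifies),
      qualifying_types = paste(.data$type[.data$qualifies], collapse = ";"),
      .groups = "drop"
    )
  structure(list(table = table, assignment = assignment),
            class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat("<cluster_annotation>\n")
  print(as.data.frame(x$assignment), row.names = FALSE)
  invisible(x)
}

#' @rdname annotate_clusters
#' @param x A `cluster_annotation` object.
#' @param ... Unused.
#' @export
tidy.cluster_annotation <- function(x, ...) {
  dplyr::left_join(x$table, x$assignment, by = "cluster")
}

#' Distance-to-plaque histogram per annotated cell type
#'
#' For each annotated type, the histogram of cell-centroid distance to the
#' nearest plaque, renormalized by the ring area of each bin (the same
#' quadratic-area correction as [distance_profile()]). Types without cells
#' are skipped with a warning; with no plaques all distances are infinite
#' and the result is empty.
#'
#' @param cells Data frame with `x`, `y` (um) and a `type` column (e.g.
#'   cluster assignment mapped onto cells).
#' @param field A `plaque_field`.
#' @param bin_width,max_range Histogram geometry, um.
#' @return Tibble: `type`, `bin`, `bin_lo`, `bin_hi`, `count`,
#'   `annulus_area`, `density` (cells per um^2 of ring).
#' @export
celltype_distance_histogram <- function(cells, field, bin_width = 5,
                                        max_range = 200) {
  stopifnot(all(c("x", "y", "type") %in% names(cells)))
  n_bins <- as.integer(round(max_range / bin_width))
  qd <- query_distance(field, cells)
  qd <- dplyr::filter(qd, .data$in_bounds)
  if (all(!is.finite(qd$distance))) {
    warn("no plaques: all distances infinite, empty histogram.")
    return(tibble(type = character(), bin = integer(), bin_lo = numeric(),
                  bin_hi = numeric(), count = numeric(),
                  annulus_area = numeric(), density = numeric()))
  }
  areas <- annulus_areas(n_bins, bin_width)
  types <- unique(cells$type)
  purrr::map_dfr(types, function(ty) {
    d <- qd$distance[qd$type == ty & is.finite(qd$distance)]
    if (length(d) == 0) {
      warn(sprintf("type '%s' has no cells with finite distance; skipped.", ty))
      return(NULL)
    }
    bin <- floor(d / bin_width) + 1
    bin <- bin[bin >= 1 & bin <= n_bins]
    counts <- tabulate(bin, nbins = n_bins)
    tibble(type = ty, bin = seq_len(n_bins),
           bin_lo = (seq_len(n_bins) - 1) * bin_width,
           bin_hi = seq_len(n_bins) * bin_width,
           count = counts, annulus_area = areas,
           density = counts / areas)
  })
}
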