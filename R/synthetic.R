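#' Enrichment specification for a synthetic gene
#'
#' Declares the planted spatial structure of one gene: a baseline transcript
#' intensity outside the plaque neighbourhood and multiplicative enrichment
#' folds inside the plaque and in the adjacent zone.
#' `fold_inside = fold_adjacent = 1` defines a spatially homogeneous (null)
#' gene.
#'
#' @param gene Gene name.
#' @param baseline_intensity Points per um^2 in the outside zone (>= 0).
#' @param fold_inside,fold_adjacent Nonnegative multipliers.
#' @return One-row tibble.
#' @export
enrichment_spec <- function(gene, baseline_intensity,
                            fold_inside = 1, fold_adjacent = 1) {
  stopifnot(baseline_intensity >= 0, fold_inside >= 0, fold_adjacent >= 0)
  tibble(gene = gene, baseline_intensity = baseline_intensity,
         fold_inside = fold_inside, fold_adjacent = fold_adjacent)
}

#' Cell-type specification for the synthetic cell generator
#'
#' @param type_name Type label.
#' @param marker_genes Non-empty character vector, subset of the panel.
#' @param marker_mean Expected count of marker genes (must exceed
#'   `background_mean`: planted separability).
#' @param background_mean Expected count of non-marker genes.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param spatial_rule `"uniform"` or `"plaque_adjacent"` placement.
#' @return A list of class `cell_type_spec`.
#' @export
cell_type_spec <- function(type_name, marker_genes, marker_mean = 10,
                           background_mean = 1, dispersion = 2,
                           spatial_rule = c("uniform", "plaque_adjacent")) {
  spatial_rule <- match.arg(spatial_rule)
  if (length(marker_genes) == 0) abort("empty marker gene list.")
  if (marker_mean <= background_mean) {
    abort("`marker_mean` must exceed `background_mean`.")
  }
  structure(list(type_name = type_name, marker_genes = marker_genes,
                 marker_mean = marker_mean, background_mean = background_mean,
                 dispersion = dispersion, spatial_rule = spatial_rule),
            class = "cell_type_spec")
}

#' Simulate an amyloid-stain image with known plaques
#'
#' Plaques are bright non-overlapping disks on a dark Gaussian-noise
#' background, fully inside the frame. Morphological realism is not
#' attempted: every downstream statistic depends only on the plaque mask
#' and distances, for which disks suffice. The default
#' foreground/background separation is 16x the noise SD, so thresholding
#' recovers the mask.
#'
#' @param n_plaques Number of plaques (>= 0).
#' @param radius_range Disk radius interval, um.
#' @param image_size `c(rows, cols)` in px (scalar = square).
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param background,foreground Mean intensity levels.
#' @param scale A [pixel_scale()] (generator default: 1 um/px).
#' @param seed RNG seed; identical seeds give identical output.
#' @param max_tries Placement retries before giving up.
#' @return List: `image` ([stain_image()]), `mask` (true label matrix,
#'   raster-order ids), `truth` (tibble of centers/radii, um).
#' @export
make_plaque_image <- function(n_plaques = 5, radius_range = c(10, 20),
                              image_size = c(400, 400), noise_sd = 0.05,
                              background = 0.1, foreground = 0.9,
                              scale = pixel_scale(1), seed = 1,
                              max_tries = 1000) {
  scale <- as_pixel_scale(scale)
  s <- scale$microns_per_pixel
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  nr <- image_size[1]; nc <- image_size[2]
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    for (i in seq_len(n_plaques)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r <- runif(1, radius_range[1], radius_range[2])
        margin <- r / s + 1
        cx <- runif(1, margin, nc - 1 - margin) * s
        cy <- runif(1, margin, nr - 1 - margin) * s
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                radii + r + 2 * s)) {
          centers <- rbind(centers, c(cx, cy))
          radii <- c(radii, r)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not place plaque %d of %d after %d tries; use fewer or smaller plaques.",
          i, n_plaques, max_tries))
      }
    }
    # label mask: disks on the pixel-centre grid
    px <- (col(matrix(0, nr, nc)) - 1) * s
    py <- (row(matrix(0, nr, nc)) - 1) * s
    mask <- matrix(0L, nr, nc)
    for (i in seq_len(n_plaques)) {
      inside <- (px - centers[i, 1])^2 + (py - centers[i, 2])^2 <= radii[i]^2
      mask[inside] <- i
    }
    # renumber labels in raster order of first pixel (matching segmentation)
    relabeled <- .label_components_8(mask > 0)
    id_map <- integer(n_plaques)
    for (i in seq_len(n_plaques)) {
      id_map[i] <- relabeled[mask == i][1]
    }
    img <- matrix(rnorm(nr * nc, background, noise_sd), nr, nc)
    img[mask > 0] <- rnorm(sum(mask > 0), foreground, noise_sd)
    truth <- tibble(
      plaque_id = if (n_plaques > 0) id_map else integer(),
      center_x = centers[, 1], center_y = centers[, 2], radius = radii
    ) |> dplyr::arrange(.data$plaque_id)
    list(image = stain_image(img, scale = scale, channel = "amyloid"),
         mask = relabeled, truth = truth)
  })
}

# zone label per pixel of a mask (1 = inside, 2 = adjacent, 3 = outside)
zone_grid <- function(mask, zone_radius, scale) {
  s <- as_pixel_scale(scale)$microns_per_pixel
  if (max(mask) > 0) {
    d <- as.matrix(EBImage::distmap(1 - (mask > 0))) * s
  } else {
    d <- matrix(Inf, nrow(mask), ncol(mask))
  }
  ifelse(d == 0, 1L, ifelse(d <= zone_radius, 2L, 3L))
}

#' Simulate transcript point patterns around plaques
#'
#' For every gene of `specs`, an inhomogeneous Poisson point process whose
#' intensity is piecewise constant over the three proximity zones of the
#' plaque mask: `baseline * fold(zone)`. Points are placed uniformly within
#' the zone (uniform pixel choice plus sub-pixel jitter), so realized
#' per-zone counts are Poisson with mean `intensity * zone area`.
#'
#' @param mask True plaque label matrix (e.g. from [make_plaque_image()]).
#' @param specs Tibble of [enrichment_spec()] rows.
#' @param zone_radius Adjacent-zone width, um.
#' @param scale A [pixel_scale()].
#' @param seed RNG seed.
#' @return List: `transcripts` (tibble `x`, `y`, `gene`), `truth` (tibble
#'   gene x zone: intensity, zone area, expected and realized counts).
#' @export
make_transcripts <- function(mask, specs, zone_radius = 69,
                             scale = pixel_scale(1), seed = 1) {
  stopifnot(nrow(specs) > 0)
  scale <- as_pixel_scale(scale)
  s <- scale$microns_per_pixel
  zg <- zone_grid(mask, zone_radius, scale)
  pixel_area <- s^2
  zone_names <- c("inside", "adjacent", "outside")
  zone_pix <- lapply(1:3, function(z) which(zg == z))
  zone_area <- lengths(zone_pix) * pixel_area
  nr <- nrow(mask)
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (i in seq_len(nrow(specs))) {
      folds <- c(specs$fold_inside[i], specs$fold_adjacent[i], 1)
      lambda <- specs$baseline_intensity[i] * folds
      expected <- lambda * zone_area
      n_z <- rpois(3, expected)
      for (z in 1:3) {
        if (n_z[z] > 0 && length(zone_pix[[z]]) > 0) {
          pix <- sample(zone_pix[[z]], n_z[z], replace = TRUE)
          cc <- ((pix - 1) %/% nr)     # 0-based col
          rr <- ((pix - 1) %% nr)      # 0-based row
          rows[[length(rows) + 1]] <- tibble(
            x = (cc + runif(n_z[z], -0.5, 0.5)) * s,
            y = (rr + runif(n_z[z], -0.5, 0.5)) * s,
            gene = specs$gene[i]
          )
        }
      }
      truth[[i]] <- tibble(
        gene = specs$gene[i], zone = zone_names,
        intensity = lambda, zone_area_um2 = zone_area,
        expected_count = expected,
        realized_count = ifelse(zone_area > 0, n_z, 0)
      )
    }
    transcripts <- dplyr::bind_rows(rows)
    if (nrow(transcripts) == 0) {
      warn("all intensities zero (or empty zones): empty transcript table.")
      transcripts <- tibble(x = numeric(), y = numeric(), gene = character())
    }
    list(transcripts = transcripts, truth = dplyr::bind_rows(truth))
  })
}

#' Simulate a segmented-cell count matrix with planted cell types
#'
#' Cells of each type draw negative-binomial counts with mean `marker_mean`
#' on the type's marker genes and `background_mean` elsewhere. Types with
#' `spatial_rule = "plaque_adjacent"` are placed at distance
#' `0 < d <= zone_radius` from the mask's plaques; `"uniform"` types
#' anywhere in the window.
#'
#' @param types List of [cell_type_spec()] objects.
#' @param n_cells_per_type Scalar or one count per type.
#' @param panel Character vector of panel genes (superset of all markers).
#' @param mask Plaque label matrix defining the window (and adjacency).
#' @param zone_radius Adjacent-zone width, um.
#' @param scale A [pixel_scale()].
#' @param seed RNG seed.
#' @return List: `cells` ([cell_matrix()]), `true_labels` (character).
#' @export
make_cells <- function(types, n_cells_per_type = 200, panel, mask,
                       zone_radius = 69, scale = pixel_scale(1), seed = 1) {
  if (inherits(types, "cell_type_spec")) types <- list(types)
  markers <- unlist(lapply(types, `[[`, "marker_genes"))
  if (!all(markers %in% panel)) {
    abort(sprintf("marker gene(s) not in panel: %s",
                  paste(setdiff(markers, panel), collapse = ", ")))
  }
  n_per <- rep(n_cells_per_type, length.out = length(types))
  scale <- as_pixel_scale(scale)
  s <- scale$microns_per_pixel
  zg <- zone_grid(mask, zone_radius, scale)
  nr <- nrow(mask)
  with_seed(seed, {
    count_blocks <- list()
    pos <- list()
    labels <- character(0)
    for (t in seq_along(types)) {
      ty <- types[[t]]
      n <- n_per[t]
      if (n == 0) next
      mu <- ifelse(panel %in% ty$marker_genes, ty$marker_mean,
                   ty$background_mean)
      block <- matrix(
        rnbinom(n * length(panel), size = ty$dispersion,
                mu = rep(mu, each = n)),
        nrow = n, ncol = length(panel), dimnames = list(NULL, panel)
      )
      pix_pool <- if (ty$spatial_rule == "plaque_adjacent") {
        which(zg == 2L)
      } else {
        seq_along(zg)
      }
      if (length(pix_pool) == 0) {
        abort("no plaque-adjacent pixels available for placement.")
      }
      pix <- sample(pix_pool, n, replace = TRUE)
      pos[[length(pos) + 1]] <- tibble(
        x = (((pix - 1) %/% nr) + runif(n, -0.5, 0.5)) * s,
        y = (((pix - 1) %% nr) + runif(n, -0.5, 0.5)) * s
      )
      count_blocks[[length(count_blocks) + 1]] <- block
      labels <- c(labels, rep(ty$type_name, n))
    }
    if (length(count_blocks) == 0) {
      counts <- matrix(integer(0), 0, length(panel),
                       dimnames = list(NULL, panel))
      cells <- tibble(cell = character(), x = numeric(), y = numeric())
      return(list(cells = cell_matrix(counts, cells),
                  true_labels = character(0)))
    }
    counts <- do.call(rbind, count_blocks)
    xy <- dplyr::bind_rows(pos)
    cells <- tibble(cell = sprintf("cell_%04d", seq_len(nrow(counts))),
                    x = xy$x, y = xy$y)
    list(cells = cell_matrix(counts, cells), true_labels = labels)
  })
}

#' Simulate paired DAPI / T-cell-channel images
#'
#' Nuclei are Gaussian blobs at non-overlapping centres on an 8-bit-like
#' intensity scale; a random subset of them is covered by bright disks in
#' the T-cell channel. An optional linear background gradient (e.g. within
#' the range the rolling-ball subtraction removes) can be added to both
#' channels.
#'
#' @param n_nuclei,n_tcells Object counts (`n_tcells <= n_nuclei`).
#' @param image_size `c(rows, cols)` px.
#' @param nucleus_sigma Gaussian blob SD, px.
#' @param nucleus_amplitude,background,noise_sd DAPI intensity parameters.
#' @param tcell_radius,tcell_amplitude T-cell-channel disk geometry.
#' @param min_separation Minimum centre-to-centre distance, px.
#' @param gradient_amplitude Linear left-to-right background ramp amplitude.
#' @param scale A [pixel_scale()].
#' @param seed RNG seed.
#' @param max_tries Placement retries.
#' @return List: `dapi`, `tcell` ([stain_image()]s), `truth` (tibble of
#'   nucleus centres in um with `is_tcell` flags).
#' @export
make_if_images <- function(n_nuclei = 50, n_tcells = 5,
                           image_size = c(400, 400), nucleus_sigma = 3,
                           nucleus_amplitude = 150, background = 10,
                           noise_sd = 2, tcell_radius = 8,
                           tcell_amplitude = 200, min_separation = 30,
                           gradient_amplitude = 0, scale = pixel_scale(1),
                           seed = 1, max_tries = 5000) {
  if (n_tcells > n_nuclei) abort("`n_tcells` must be <= `n_nuclei`.")
  scale <- as_pixel_scale(scale)
  s <- scale$microns_per_pixel
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  nr <- image_size[1]; nc <- image_size[2]
  margin <- max(4 * nucleus_sigma, tcell_radius + 2)
  with_seed(seed, {
    cx <- numeric(0); cy <- numeric(0)
    for (i in seq_len(n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        px <- runif(1, margin, nc - 1 - margin)
        py <- runif(1, margin, nr - 1 - margin)
        if (length(cx) == 0 ||
            min(sqrt((cx - px)^2 + (cy - py)^2)) >= min_separation) {
          cx <- c(cx, px); cy <- c(cy, py)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not place nucleus %d of %d; reduce n_nuclei or min_separation.",
          i, n_nuclei))
      }
    }
    gx <- (col(matrix(0, nr, nc)) - 1)
    gy <- (row(matrix(0, nr, nc)) - 1)
    ramp <- if (gradient_amplitude > 0) gradient_amplitude * gx / (nc - 1) else 0
    dapi <- matrix(rnorm(nr * nc, background, noise_sd), nr, nc) + ramp
    for (i in seq_along(cx)) {
      dapi <- dapi + nucleus_amplitude *
        exp(-((gx - cx[i])^2 + (gy - cy[i])^2) / (2 * nucleus_sigma^2))
    }
    dapi <- pmax(dapi, 0)
    tflag <- rep(FALSE, n_nuclei)
    if (n_tcells > 0) tflag[sample(n_nuclei, n_tcells)] <- TRUE
    tcell <- matrix(rnorm(nr * nc, background / 2, noise_sd), nr, nc) + ramp
    for (i in which(tflag)) {
      disk <- (gx - cx[i])^2 + (gy - cy[i])^2 <= tcell_radius^2
      tcell[disk] <- tcell[disk] + tcell_amplitude
    }
    tcell <- pmax(tcell, 0)
    truth <- tibble(x = cx * s, y = cy * s, is_tcell = tflag)
    list(dapi = stain_image(dapi, scale = scale, channel = "dapi"),
         tcell = stain_image(tcell, scale = scale, channel = "tcell"),
         truth = truth)
  })
}
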