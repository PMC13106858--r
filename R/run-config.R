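#' Default marker panels
#'
#' The gene sets used throughout the spatial analyses: interferon-stimulated
#' genes (ISG), T-cell exhaustion markers, T-cell markers, and microglia
#' markers. Sets are matched against each dataset's panel at use time;
#' genes absent from a dataset are dropped with a logged warning, never
#' silently. (`Cd163l1n` in the T-cell list matches no standard mouse symbol;
#' it is carried verbatim and simply drops when absent.)
#'
#' @return Named list of character vectors.
#' @export
default_gene_panels <- function() {
  list(
    isg = c("Ifit1", "Ifit2", "Irf7", "Ifnar1", "Usp18", "Isg15", "Cxcl10"),
    exhaustion = c("Pdcd1", "Havcr2", "Lag3", "Tigit", "Ctla4", "Cd244",
                   "Cd160", "Cd96", "Cd38", "Tox"),
    tcell = c("Cd3e", "Cd4", "Cd8b1", "Foxp3", "Trbc", "Trdc", "Cd163l1n",
              "Ccr7"),
    microglia = c("Cst3", "Hexb", "Tyrobp", "Ctsd", "P2ry12", "Tmem119",
                  "Tgfbr1", "Olfml3", "Cst7", "Apoe", "Lpl", "Trem2",
                  "Srgap2", "Nav2")
  )
}

#' Analysis run configuration
#'
#' Bundles the tunable parameters shared across the pipeline. The 69 um zone
#' radius is the plaque-adjacent band width (500 px on rendered slides at
#' 0.138 um/px); all other defaults are package choices exposed here.
#'
#' @param zone_radius Plaque-adjacent zone width, um.
#' @param pixel_scale A [pixel_scale()] (or um/px number).
#' @param plaque_threshold_method `"otsu"` or `"fixed"`.
#' @param plaque_fixed_threshold Threshold on the normalized `[0,1]` scale
#'   when `plaque_threshold_method = "fixed"`.
#' @param plaque_min_area Minimum plaque component area, um^2.
#' @param histogram_bin_width Distance-histogram bin width, um.
#' @param histogram_max_range Distance-histogram range, um (multiple of the
#'   bin width).
#' @param rng_seed Integer seed used for all stochastic steps.
#' @param gene_panels Named list of non-empty gene sets with unique names.
#' @return An object of class `run_config`.
#' @export
run_config <- function(zone_radius = 69,
                       pixel_scale = plaqueniche::pixel_scale(),
                       plaque_threshold_method = c("otsu", "fixed"),
                       plaque_fixed_threshold = NULL,
                       plaque_min_area = 10,
                       histogram_bin_width = 5,
                       histogram_max_range = 200,
                       rng_seed = 1L,
                       gene_panels = default_gene_panels()) {
  plaque_threshold_method <- match.arg(plaque_threshold_method)
  if (!is.numeric(zone_radius) || zone_radius <= 0) {
    abort("`zone_radius` must be > 0.")
  }
  if (!is.numeric(histogram_bin_width) || histogram_bin_width <= 0) {
    abort("`histogram_bin_width` must be > 0.")
  }
  if (length(gene_panels) > 0) {
    if (is.null(names(gene_panels)) || anyDuplicated(names(gene_panels))) {
      abort("gene panel names must be present and unique.")
    }
    if (any(lengths(gene_panels) == 0)) abort("empty gene panel.")
  }
  structure(list(
    zone_radius = zone_radius,
    pixel_scale = as_pixel_scale(pixel_scale),
    plaque_threshold_method = plaque_threshold_method,
    plaque_fixed_threshold = plaque_fixed_threshold,
    plaque_min_area = plaque_min_area,
    histogram_bin_width = histogram_bin_width,
    histogram_max_range = histogram_max_range,
    rng_seed = as.integer(rng_seed),
    gene_panels = gene_panels
  ), class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' One flat YAML document mirroring [run_config()]; fields not present fall
#' back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "...")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warn(sprintf("ignoring unknown config fields: %s", paste(extra, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$pixel_scale <- out$pixel_scale$microns_per_pixel
  yaml::write_yaml(out, path)
  invisible(path)
}
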