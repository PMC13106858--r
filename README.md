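# plaqueniche

Spatial analysis of the amyloid plaque niche: how transcripts, cell types
and T cells organise around amyloid-β deposits.

In Alzheimer's-model cortex, plaques restructure their surroundings —
microglia switch state, interferon-stimulated genes (ISGs) such as *Cxcl10*
are induced near deposits, and T cells infiltrate the neighbourhood.
`plaqueniche` turns the raw outputs of a targeted spatial-transcriptomics
run (an amyloid-stain image and single-molecule transcript coordinates, or
a segmented cell × gene matrix) and of immunofluorescence imaging (DAPI +
T-cell-marker channels) into quantitative neighbourhood statistics, and
ships a synthetic-data module so that every stage is testable against known
ground truth without tissue data.

## The model in brief

Everything is anchored to the Euclidean distance *d* of a point to the
nearest plaque, computed from a thresholded, 8-connected-labelled stain
image via an exact distance transform. Tissue is partitioned into three
zones:

| zone | definition |
|---|---|
| inside | *d* = 0 (on a plaque) |
| plaque-adjacent | 0 < *d* ≤ 69 µm (500 px at 0.138 µm/px) |
| outside | *d* > 69 µm |

On top of this the package computes:

* **zone densities** — transcripts per µm² of zone area, globally or per
  plaque, compared with Kruskal–Wallis + Dunn post hoc;
* **annulus-renormalised distance profiles** — reference-centred distance
  histograms divided by ring areas π w² (2b − 1), flat at intensity λ under
  spatial randomness; per-gene, per marker set, or gene-vs-panel
  overrepresentation ratios;
* **cell typing** — missingness/count filtering, analytic Pearson residuals
  (x − μ)/√(μ + μ²/θ), PCA + Leiden clustering, expression-matched gene-set
  scores, and cluster annotation by the separation score
  s = (mean_in − mean_out)/(sd_in + sd_out) > 1;
* **T-cell counting** — rolling-ball background subtraction, Gaussian blur,
  prominence-based maxima as nuclei, channel-mask intersection as T cells,
  90-px per-plaque counts, and Spearman correlation with plaque burden.

## Worked example

Simulate a stained section with six plaques, plant a 5-fold
plaque-neighbourhood enrichment for *Cxcl10* and a spatially uniform
control (*Hexb*), and recover the structure:

```r
library(plaqueniche)
library(dplyr)

sim   <- make_plaque_image(n_plaques = 6, image_size = c(400, 400), seed = 42)
field <- sim$image |> segment_plaques(min_area = 10) |> distance_field()

specs <- bind_rows(
  enrichment_spec("Cxcl10", 0.002, fold_inside = 5, fold_adjacent = 5),
  enrichment_spec("Hexb",   0.002))
tr    <- make_transcripts(sim$mask, specs, seed = 7)

zones <- assign_zones(field, tr$transcripts)
zone_density(zones, zone_areas(field))
#>     gene     zone transcript_count zone_area_um2 area_defined density
#> 1 Cxcl10   inside               82          6420         TRUE 0.01277
#> 2 Cxcl10 adjacent              789         82386         TRUE 0.00958
#> 3 Cxcl10  outside              152         71194         TRUE 0.00214
#> 4   Hexb   inside               19          6420         TRUE 0.00296
#> 5   Hexb adjacent              173         82386         TRUE 0.00210
#> 6   Hexb  outside              150         71194         TRUE 0.00211
```

The planted gene's adjacent density is ~4.5× its outside density (the
planted fold is 5; inside adds Poisson noise over a small area), while the
uniform control is flat across zones. Testing the contrast at plaque level:

```r
pp <- zone_density(zones, zone_areas(field, per_plaque = TRUE), per_plaque = TRUE)
kruskal_dunn(filter(pp, gene == "Cxcl10"), density, zone)
#> Kruskal-Wallis: H = 12.78, df = 2, p = 0.001675 (n = 18)
#> Dunn pairwise (holm-adjusted):
#>          comparison        z        p_raw       p_adj
#>   inside - adjacent 1.189624 0.2341943049 0.234194305
#>    inside - outside 3.514797 0.0004400895 0.001320268
#>  adjacent - outside 2.325174 0.0200626739 0.040125348
```

Six plaques × three zones give 18 per-plaque densities; the omnibus test
rejects homogeneity and Dunn's post hoc localises the contrast to the
plaque neighbourhood versus outside. `autoplot()` methods exist for fields,
zone-density tables, distance profiles, count results and correlation fits;
`tidy()`/`glance()` return the statistics as tibbles.

The same grammar covers the other branches: `distance_profile()` /
`marker_set_profile()` / `relative_overrepresentation()` for
point-pattern colocalization, `filter_matrix() |> pearson_residuals() |>
reduce_and_cluster()` plus `score_gene_set()` and `annotate_clusters()`
for cell typing, and `make_if_images()` → `subtract_background()` →
`detect_nuclei()` → `count_tcells()` → `tcells_per_plaque()` /
`correlate()` for immunofluorescence counting.

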