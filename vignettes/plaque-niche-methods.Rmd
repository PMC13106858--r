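---
title: "Quantifying the amyloid plaque niche: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the amyloid plaque niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqueniche)
```

## The problem

Amyloid-β plaques reorganise the tissue around them: microglia change state,
interferon-stimulated genes (ISGs) are induced, and T cells accumulate in the
plaque neighbourhood. `plaqueniche` quantifies this spatial reorganisation
from three kinds of raw material:

* an **amyloid-stain image** (pFTAA / Thioflavin S channel) plus a table of
  **single-molecule transcript coordinates** (targeted smFISH /
  Molecular Cartography point exports),
* a **segmented cell × gene count matrix** with cell centroids, and
* paired **DAPI / T-cell-marker immunofluorescence images**.

Every analysis is anchored to the same geometric object: the Euclidean
distance `d` of a point to the nearest plaque.

## The three-zone model

Plaques are segmented from the min–max-normalised stain image by a global
threshold (Otsu by default; a fixed threshold on the `[0, 1]` scale is
available because staining protocols differ), labelled with 8-connected
components, and filtered by a minimum area (default 10 µm², removing
single-pixel noise). The background's exact Euclidean distance transform
then partitions tissue into

* **inside** — `d = 0` (on a plaque pixel),
* **plaque-adjacent** — `0 < d ≤ 69 µm`, and
* **outside** — `d > 69 µm`.

The 69 µm zone radius corresponds to 500 px on rendered assay slides, which
fixes the default pixel scale at 0.138 µm/px; both are configurable in
`run_config()`. The upper zone bound is closed: a point at exactly 69 µm is
adjacent. Transcript densities are counts divided by the pixel-counted zone
area clipped to the imaged window (outside an imaged window no density is
defined), either globally or per plaque, where every pixel and point is
attributed to its nearest plaque with ties broken deterministically toward
the lower plaque id. Plaques touching the image border are kept but flagged,
because their zones are truncated by the field of view.

## Annulus-renormalised distance profiles

Colocalization of two markers is measured reference-centrically: for every
transcript of the reference ("marker 2"), the histogram of its distances to
all marker-1 transcripts is computed with equal-width bins (default 5 µm up
to 200 µm, resolving the 69 µm scale with 13 bins); the histograms are
averaged over references and each bin is divided by its ring area
`π w² (2b − 1)`. Under complete spatial randomness with intensity λ the
profile is flat at λ, which is the package's main calibration property. No
window edge correction is applied (matching the published procedure);
flatness tests therefore keep references at least `max_range` from the
border. Marker-set profiles (e.g. the T-cell or microglia panels of
`default_gene_panels()`) are per-gene profiles averaged bin-wise.
Gene-versus-panel overrepresentation uses probability-density histograms of
distance-to-plaque for the gene and for all panel transcripts pooled, both
ring-renormalised, and reports their per-bin ratio. Because both histograms
integrate to one, overrepresentation near the plaque necessarily appears as
a ratio below one in the tail; the units are relative, not absolute
intensities.

## Segmentation-based branch

Cell-level analysis mirrors the standard single-cell workflow, specialised
to a targeted marker panel:

1. **Missingness filter.** Marker panels differ between samples, so a
   cell × gene entry can be unmeasured. Genes with too many missing entries
   (default 60 000, the full-dataset scale) are removed *before* the
   remaining missing values are imputed to zero; cells then need ≥ 20 total
   counts. Keeping "missing" distinct from "zero" until this step is why
   the MTX reader stores absent entries as `NA`.
2. **Analytic Pearson residuals.** `r = (x − μ)/sqrt(μ + μ²/θ)` with
   `μ = rowsum × colsum / total`, `θ = 100`, clipped at `±sqrt(n_cells)` —
   the established defaults for this normalisation; `θ → ∞` recovers
   Poisson residuals.
3. **PCA + Leiden.** Centred PCA (default 20 components), a kNN graph
   (k = 30) in PC space, Leiden community detection with the modularity
   objective at resolution 0.5 and a fixed seed. The defaults were chosen
   so that clearly separated expression types resolve into their natural
   communities on panels of tens of markers; note that modularity is
   scale-dependent, so reproducing a partition on resampled data requires
   fixing the resolution.
4. **Gene-set scores.** Mean expression of a set minus the mean of an
   expression-matched control pool. Controls are drawn per set gene from
   the non-set genes nearest in mean expression (window ≈ panel size /
   `n_bins`, at least 4). Equal-frequency *bins* — the classic
   construction — degenerate on desk-scale panels, where a bin can contain
   only the set gene itself and the score collapses to zero; nearest-rank
   matching is the same idea made robust to panel size. Scoring the whole
   panel against itself gives exactly zero.
5. **Cluster annotation.** A cluster is assigned a type when the
   separation `s = (mean_in − mean_out)/(sd_in + sd_out) > 1`, with
   population standard deviations (the array default; the threshold makes
   `s` unit-free and invariant to shifting or positively scaling all
   scores). Among several qualifying types the argmax is assigned and all
   qualifiers are reported.

Batch integration is out of scope here (synthetic data are single-batch);
`reduce_and_cluster()` accepts any residual matrix, so a pre-integrated
embedding can be substituted upstream.

## Immunofluorescence counting

The counting chain reimplements a classic ImageJ macro: rolling-ball
background subtraction (grayscale opening with a flat disc of radius 30 px,
with edge-replicated padding so the estimate does not dip at borders),
Gaussian blur (the tool's "radius" is interpreted as σ = 5 px), and maxima
detection by topographic prominence (≥ 1 on the native, 8-bit-like
intensity scale). Prominence merges sub-peaks of one nucleus while keeping
distinct nuclei apart; plateaus resolve deterministically to the first
pixel in raster order, and maxima within `2σ` of the border are discarded
because smoothing is unreliable there. A nucleus is a T cell when its point
falls inside the thresholded T-cell-channel mask. The threshold is relative
(min–max scale) by default; an absolute native-scale threshold is available
because the published procedure set thresholds per image by eye, and a
relative threshold is degenerate on a channel that carries no signal at
all. Per-plaque counts assign each flagged T cell to its nearest plaque
centre within 90 px, preventing double counting where circles overlap.

## Statistics

Zone contrasts use the Kruskal–Wallis omnibus (midranks, tie-corrected)
with Dunn's pairwise z post hoc, Holm-adjusted by default (Bonferroni by
flag). The statistical unit is the per-plaque density — the published
figures do not state whether plaques, sections or transcripts were the
unit, and per-plaque avoids pseudo-replication from counting transcripts as
observations. Correlations (e.g. T-cell frequency vs plaque burden) are
Spearman's ρ with an exact p-value for n ≤ 9 without ties, plus an ordinary
least-squares line with confidence band for display.

**A caveat the synthetic null makes visible.** Under a homogeneous Poisson
transcript process, per-plaque zone densities share their mean but not
their sampling variance: the inside zone of a 10–20 µm plaque covers
10²–10³ µm² while its adjacent ring covers ~2 × 10⁴ µm², so inside
densities are far noisier than adjacent ones at any intensity (the sd
ratio is the square root of the area ratio, independent of λ). The three
groups are therefore not exchangeable even under the null, and the
plaque-level rank test is mildly anticonservative: across 5 000 null
replicates at the package's default study conditions it rejects at
α = 0.05 about 7–8 % of the time, rather than 5 %. The test itself is
correctly calibrated — on groups drawn from one distribution its level is
nominal — so the inflation is a property of using plaques as the unit with
unequal zone areas. Plaque-level zone p-values near the threshold should
be read with this in mind.

## The synthetic-data module

Every pipeline input can be generated with known ground truth:

* `make_plaque_image()` — non-overlapping bright disks on Gaussian noise.
  Defaults: 10–20 µm radii, foreground/background separation 16× the noise
  sd (so segmentation recovers the mask essentially pixel-perfectly), and a
  1 µm/px grid — coarse enough for fast simulation while resolving the
  69 µm zone geometry; distances are in µm throughout, so the grid choice
  does not touch the statistics. Disks, not realistic plaque morphology:
  every statistic tested depends only on the mask and distances.
* `make_transcripts()` — per gene, an inhomogeneous Poisson process with
  piecewise-constant intensity `baseline × fold(zone)`; `fold = 1` is the
  CSR null. Study-scale defaults in the tests use baselines of
  0.002–0.08 µm⁻² (hundreds to tens of thousands of points per section),
  matching abundant panel markers at desk scale.
* `make_cells()` — negative-binomial counts (marker mean 10, background
  mean 1, dispersion 2) with uniform or plaque-adjacent placement; the
  marker/background separation is the planted structure that clustering
  and annotation must recover.
* `make_if_images()` — Gaussian nucleus blobs (σ = 3 px, amplitude 150 on
  a background of 10 with noise sd 2 — an 8-bit-like scale) at centres
  ≥ 30 px apart, and bright disks over a chosen subset in the T-cell
  channel.

All generators are deterministic given a seed and restore the caller's RNG
state. What the synthetic data do **not** emulate: optical crowding,
segmentation errors, batch effects, irregular plaque morphology and
spatially varying background expression. Passing tests therefore validate
the *computations* — geometry, conservation, calibration, recovery of
planted effects — not robustness to those real-data artefacts.

## Numerical choices and degenerate inputs

* Distance transforms are exact (verified against brute force to 1e-6 µm);
  point lookups snap to the nearest pixel centre, bounding the error by the
  pixel diagonal.
* An empty plaque set yields an all-`Inf` distance field; zone assignment
  then warns and classifies everything as outside.
* A constant image cannot be Otsu-thresholded (error) and min–max
  normalisation of it is flagged degenerate.
* Histogram bins are `[lo, hi)`; `max_range` must be a multiple of the bin
  width; ring areas match `π w² (2b − 1)` to machine precision.
* Problem sizes in the test-suite simulations (300–600 µm windows, 12
  plaques, 100-seed Monte Carlo loops, 5 000 null replicates, 20-seed
  recovery runs) were chosen as the smallest scales at which the planted
  effects and calibration bands are clearly resolved.

## Known limitations

* No edge correction in distance profiles (fidelity to the published
  procedure over statistical optimality).
* The plaque-level rank test's mild anticonservativeness under the CSR
  null, described above.
* Parenchymal vs vascular plaque classification, batch integration, and
  cohort-level (animal-wise) statistics are out of scope.
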