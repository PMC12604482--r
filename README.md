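# craters

Quantification of CRATERs — *cancer regions of antigen presentation and T
cell engagement and retention* — in tumor microscopy. CRATERs are
pocket-shaped gaps at the stroma–melanoma interface where CD8+ T cells
accumulate and engage tumor cells; this package implements the image
computations that identify and measure them, for three experimental
systems:

* **Zebrafish 3D confocal stacks** — tumor segmentation (Gaussian
  smoothing + Otsu), bright-cell exclusion, CRATER extraction by a 3D
  **black top-hat** (`open(close(T, K40) \ T, K2)` with a 40-voxel cubic
  closing kernel and 2-voxel clean-up opening), multiscale blob detection
  of CD8+ cells, and region-conditioned statistics: CRATER surface
  coverage (%), equivalent-circle diameters (μm), cell densities
  (cells/mm²) and the crater:tumor **affinity ratio**.
* **RNAscope sections** — max projection, DBSCAN-style foci filtering
  (keep a focus iff ≥ 2 other foci lie within 10 μm), Gaussian KDE cell
  calling, tumor masks with an exact 15 μm Euclidean edge band, and
  per-cell ifng focus counts.
* **Mouse tumors after T cell transfer** — polynomial surface
  `z = P(x, y)` fitted to residual-fragment centroids with empirical
  degree selection (5-fold cross-validated RMSE, degrees 2–10, one-SE
  rule), fragment-footprint projection, and **attrition** = % of the
  reconstructed surface left unoccupied.
* **Human mIF/CyCIF** — 99th-percentile channel normalization,
  rolling-ball background subtraction, per-cell features and gating,
  tumor/margin/perivascular segmentation, a rule-based CRATER classifier
  (location on the stromal–melanocytic boundary, 20–50 μm size, ≤ 2
  collagen fibers, low nuclear density, no CD31/CD105 vessels, no aSMA
  pericytes), and **CRATER linear density** per cm of
  perivascular-melanocytic boundary (PMB).
* **Annotator concordance** — instance matching at Jaccard index > 0.4,
  TP/FP/FN, precision, recall, F1 = 2·P·R/(P+R), and the mean F1 across
  annotator pairs.

Raw study imaging is not deposited, so the package ships a
synthetic-microscopy generator (`make_tumor_phantom()`,
`make_foci_phantom()`, `make_surface_phantom()`, `make_annotator_masks()`,
`make_mif_phantom()`) whose manifests carry analytically known ground
truth; every pipeline is validated against those truths and against
brute-force oracles.

## Worked example

```r
library(craters)

ph    <- make_tumor_phantom(seed = 1)          # one synthetic fish
tumor <- segment_tumor(ph$image, "tumor")
cr    <- segment_craters(tumor)                # black top-hat instances
masks <- region_mask_set(tumor = tumor, craters = cr,
                         spacing = ph$image$spacing)
coverage_and_sizes(masks)[c("coverage_pct", "diameters_um")]
#> $coverage_pct
#> [1] 10.73967
#>
#> $diameters_um
#> [1] 52.51511 43.14483 44.71002

cells <- assign_cell_regions(detect_cells(ph$image, "cells"),
                             masks, contact_dist = 5)
rep <- region_densities(cells, masks)
c(crater = rep$density_crater, tumor = rep$density_tumor,
  affinity = rep$affinity_ratio)
#>      crater       tumor    affinity
#> 3655.252020 1111.059673    3.289879
```

Three CRATERs of ~43–53 μm cover ~11% of the tumor surface, and the
detected CD8+ cell density inside them is ~3.3× the density on the rest
of the surface; the phantom planted a ratio of 3.93 for this seed
(`ph$truth$planted_density_ratio`), the difference coming from detection
and boundary effects at this field size.

The `analysis/` directory contains the numbered drivers that run each
study end to end and write their tables under `results/`:
`01_zebrafish_3d.R`, `02_rnascope.R`, `03_mouse_attrition.R`,
`04_human_mif.R`, `05_concordance.R`.

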