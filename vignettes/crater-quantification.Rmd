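---
title: "Quantifying CRATER immune niches: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRATER immune niches: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CRATERs are pocket-shaped indentations at the boundary between a melanoma
cell mass and the surrounding stroma in which CD8+ T cells accumulate,
engage tumor cells, and are retained. This package reimplements, as tested
R code, the image computations used to find and measure them across three
experimental systems: 3D confocal stacks of zebrafish melanoma, sectioned
mouse tumors after adoptive T cell transfer, and multiplexed
immunofluorescence (mIF/CyCIF) of human melanoma. Because the underlying
microscopy is not publicly deposited, every pipeline is exercised against
synthetic phantoms with analytically known ground truth; this vignette
records the models, the parameters that matter, and the design decisions
taken where the original description left them open.

## 1. 3D CRATER segmentation (zebrafish)

The tumor is segmented from its marker channel by Gaussian noise reduction
followed by Otsu thresholding, keeping the largest connected component.
Bright marker-positive cells can first be detected as blobs and excluded so
they do not distort the threshold. CRATERs are then extracted by a **black
top-hat** on the binary tumor mask:

    craters = open( close(T, K40) \ T , K2 )

i.e. morphological closing with a 40-voxel cubic structuring element, minus
the tumor, followed by a 2-voxel opening that removes residue arising from
the mismatch between tumor morphology and the cubic kernel. Closing with a
box of side *k* fills any surface concavity that cannot accommodate the
box; a hemispherical pocket of diameter up to roughly `k * sqrt(2)` voxels
is filled completely, so with the 40-voxel kernel the ~50 um pockets are
recovered in full.

Numerical conventions (all fixed so results are bit-stable):

* The structuring element is a cube in **voxel** units (the kernel is
  specified in voxels, not micrometres); an even-sized box is anchored at
  `floor(k/2)` (0-based) and erosion uses the same anchor, so closing is
  the mathematical `(A %+% B) %-% B` and is extensive.
* The volume is padded with background by the kernel size before closing
  and cropped afterwards, preventing phantom craters along image borders;
  components that still touch the border are flagged in the output.
* Crater instances smaller than 27 voxels (a 3-voxel cube) are discarded;
  the opening already removes most residue and the floor stabilizes
  counts.

Cell detection is multiscale difference-of-Gaussian blob detection with
scales covering cell radii of 3–8 um (T cells are ~10 um across), applied
with per-axis sigmas so anisotropic z-spacing is handled in physical
units. Two cells closer than the blob scale merge into one detection; that
is inherent to single-scale-maximum detection and is documented rather
than patched.

## 2. Spatial statistics

Distances are computed with an exact anisotropic Euclidean distance
transform (Felzenszwalb–Huttenlocher), read at each cell centroid's
nearest voxel; a cell inside a region has distance zero. Region labels
follow a fixed priority — crater, then tumor, then outside — with a
contact distance defaulting to 5 um, the "near or contacting (< 5 um)"
convention; direct overlap (`contact_dist = 0`) is exposed separately.

**Surface areas.** Region densities (cells per mm^2 of surface) and CRATER
coverage need a surface measure for voxel masks. We use the z-projected
footprint area by default: the tumors analyzed here are slab-like with the
biology on the upper face, the projected area is exactly the quantity the
phantom manifests count, and it is invariant to how the mask is sampled in
z. A spacing-aware exposed-voxel-face estimator is available as an option
(`surface_area(..., method = "voxel_face")`) for sensitivity checks; a
triangulated isosurface was considered and rejected because no installed
mesher exists and face counting plus projection bracket the answer for
the geometries involved.

**Coverage** is crater footprint area over the footprint of tumor plus
craters (the denominator includes the crater area itself; the alternative
is one flag away). **Crater diameter** is the equivalent-circle diameter
of the surface-projected footprint — a single stable number per crater.
The **affinity ratio** is crater density over tumor density and is
reported as `NA` when the tumor density is zero.

Group comparisons use the tests standard in this literature: a two-sided
Mann-Whitney U (exact for groups of up to 8 without ties — `wilcox.test`'s
exact branch — otherwise normal approximation with tie and continuity
correction), a two-sided Welch t, and a paired t for within-fish
crater-vs-tumor density comparisons. Degenerate inputs have defined
behavior: all-tied MWU returns p = 1 with a warning; exactly separated
zero-variance t groups return statistic `Inf`, p = 0, flagged.

## 3. RNAscope quantification

Stacks are max-projected to 2D. Detected cd8a transcript foci are filtered
by the neighborhood rule — keep a focus only if at least two other foci
lie within 10 um, computed with exact pairwise distances — which removes
isolated non-specific signal. The retained foci drive a Gaussian kernel
density estimate evaluated on the pixel grid in units of foci per um^2, so
the map integrates to the focus count (kernels truncated at 5 sigma; mass
within 1% for in-field points). Cells are called as local maxima of the
KDE above a density threshold; because the map is already smooth at the
bandwidth scale, a second blob-detection pass adds nothing, and plateau
maxima are merged to their centroid.

The bandwidth is not stated in the original description; the default is
**5 um** — half a T-cell diameter — so the transcript cloud of one cell
forms a single peak while cells a cell-diameter apart stay separate. The
peak threshold default (0.02 foci/um^2) sits an order of magnitude above
the density that isolated noise foci can produce and well below the peak
of a 10-focus cluster (~0.055 at these scales). Both are parameters and
are recorded in run reports.

Tumor masks come from smoothing + Otsu + disc closing; the tumor edge is
the band of pixels whose exact Euclidean distance to the tumor lies in
(0, 15] um. Using the distance transform rather than a rasterized dilation
makes the band-width guarantee exact by construction. Each ifng focus is
assigned to at most one cell — the nearest within the association radius
(default 7.5 um, the called-cell scale), ties to the lower cell id.

## 4. Mouse attrition estimator

Fragment centroids are extracted per label (exact voxel-coordinate means).
A bivariate polynomial `z = P(x, y)` is fitted by least squares for each
candidate degree 2–10 on coordinates scaled to [-1, 1] for conditioning.
"Best fit" cannot mean in-sample RMSE, which decreases monotonically with
degree, so the degree is chosen by **5-fold cross-validated RMSE with a
one-standard-error tie-break toward the lower degree**; candidates needing
more coefficients than there are points are dropped with a message. On
noiseless polynomial data the true degree is selected with numerically
zero error; on noisy phantoms the planted degree is recovered in at least
8 of 10 seeds.

Attrition is measured by discretizing the convex hull of the fragment
(x, y) cloud into 10 um grid cells and marking a cell occupied when any
fragment footprint — a disc of the fragment's equivalent-sphere radius —
covers its center; attrition is the unoccupied percentage. Footprint
projection is the default (area-faithful); centroid-only projection is an
option and the report names the mode. The estimator is checked against a
brute-force point-in-disc oracle, is monotone under fragment removal, and
is scale-equivariant.

## 5. Human mIF pipeline

Channels are normalized to their 99th percentile (clipped at 1), membrane
channels summed into a composite, the nuclear channel normalized alone.
Background subtraction is grayscale opening with a flat disc of 50 px
(rolling-ball style); the output is non-negative and never exceeds the
input. Cell segmentation itself is consumed as an input label mask (the
published pipeline used a pretrained model); per-cell features are mean
channel intensities plus centroids.

Cell phenotyping replaces the published cluster-then-manually-curate step
with a deterministic gating table (priority: Treg = CD4+FOXP3+, then
DC = CD163+CD11c+, then CD8 T, CD4 T, tumor = SOX10+, else other), with a
passthrough for externally supplied cluster labels. Manual curation is
irreproducible; gating makes the phenotype step testable. Positivity uses
the larger of the channel's Otsu threshold and an absolute floor (0.35 on
normalized intensities) so noise-only channels yield no positives.

Tumor masks come from Otsu + closing + opening; the margin is the band
within 50 um outside the tumor; enclosed holes are filtered by area
(2,000–50,000 um^2) and CD31/CD105 content into perivascular areas (PVAs),
and each PVA's boundary — the perivascular-melanocytic boundary, PMB — is
measured on its sub-pixel contour after a 3 um circular moving average
(digital contours overestimate length; the smoothing window was calibrated
on rasterized circles of known perimeter, where it is accurate to ~1–2%).
The hole-size and CD31 thresholds are not stated in the original
description and are exposed parameters with logged defaults.

The CRATER rule classifier accepts a candidate iff all of: it sits on a
stromal-melanocytic interface (PMB or outer margin, within a tolerance of
its own radius plus 10 um); equivalent diameter in 20–50 um; at most two
collagen fibers inside (counted as connected components of the thresholded
collagen channel within the polygon — an automatable proxy for visual
fiber counting); nuclear density below half the perivascular nuclear
density; no CD31+/CD105+ vessel pixels; no aSMA+ pericytes. Rejections
list every failed rule, and the classifier is monotone: relaxing any
threshold can only grow the accepted set.

Cells are assigned with the exclusion logic: overlapping a CRATER makes a
crater cell; overlapping the border but not a CRATER, a border cell;
overlapping the tumor but neither, a tumor cell. **CRATER linear density**
is accepted CRATERs per cm of PMB, with fibrotic segments excluded from
the length; the outer stromal border is measured separately so either or
both boundary classes can serve as denominator.

## 6. Annotator concordance

Instance masks from two annotators are matched by Jaccard index with a
strict threshold (JI > 0.4; boundary-equal pairs do not match), one-to-one
greedily by descending JI — the standard instance-segmentation convention;
an exhaustive optimal assignment is provided for small instances and
agrees with greedy on ≥ 95% of random phantoms. Matched pairs are TP,
unmatched first-mask objects FP, unmatched second-mask objects FN;
precision, recall and F1 follow, and the mean F1 over the three pairwise
comparisons summarizes a three-annotator study. Swapping the two masks
swaps FP and FN and leaves TP and F1 unchanged.

## 7. Synthetic phantoms: what they emulate, and what they do not

Every generator is a pure function of its arguments and seed, and every
manifest quantity is computed analytically or by direct counting on the
planted geometry — never by the pipeline under test.

* **3D tumor phantom**: a slab with a flat top face bearing ellipsoidal
  pocket indentations (depth defaulting to half the diameter), spherical
  cells, optional vessel tubes, additive Gaussian noise on a constant
  background. Defaults are the study conditions: pocket diameters around
  50 um at ~12% surface coverage, 2 um z-spacing over 1 um lateral,
  and a 4:1 crater:tumor cell-density ratio. Cells planted "on the tumor"
  keep an 8 um lateral buffer from pocket rims so that truth region labels
  are unambiguous under the 5 um contact rule; in-pocket counts are
  derived from the requested density ratio and the realized areas.
* **Foci phantom**: Gaussian clusters (default sigma 2 um, 10 foci) far
  apart relative to the 10 um filter radius, plus uniform noise labeled as
  such.
* **Surface phantom**: fragments tile the occupied region on a slightly
  jittered lattice whose footprint radius guarantees coverage of the
  occupied set; the unoccupied region is a central disc sized against the
  lattice's convex hull so the planted attrition is exactly recoverable by
  a hull-based estimator (a scattered occupied set would shrink the hull
  and bias the estimate).
* **Annotator phantom**: rectangle pairs shifted to achieve requested JIs
  (`d = round(w (1-ji)/(1+ji))`, accurate to 0.02 at the default object
  size), plus unmatched extras; infeasible requests error with the pair
  index.
* **mIF phantom**: a tumor disc with perivascular holes (CD31/CD105 spot,
  aSMA ring, dense stromal nuclei), CRATER notches carved on hole
  boundaries with one collagen fiber and one or two immune cells each, and
  one decoy candidate per disqualifying rule. PMB truth lengths use the
  closed-form perimeter of a disc union.

What the phantoms deliberately omit: realistic optics (no PSF, no
attenuation with depth), shot noise, pigment absorption, irregular tumor
shapes, touching cells, and segmentation errors in the provided cell
masks. Passing tests therefore demonstrate that the **computations** are
correct and recover planted truth under controlled conditions — not that
the pipelines are robust to every artifact of real microscopy.

## 8. Problem sizes and reproducibility

The bundled analyses and tests run at desk scale: 3D phantoms of
48 x 220 x 220 voxels (96 x 220 x 220 um), mIF phantoms of 700 x 700 px at
1 um/px, 500-fragment surface clouds, and up to 2,000-point foci sets —
sizes at which the brute-force oracles (shift-based morphology, all-pairs
distances, exhaustive matching, full MWU enumeration) remain exact and
fast while every statistic of interest is well within its sampling
tolerance. All randomness flows through explicit seeds;
`scripts/acceptance.R --seed N --out file.json` regenerates every headline
quantity from scratch.

## 9. Known limitations

* The original "Blob finder" and "Normalization" operators are
  proprietary, with unpublished parameters; the DoG detector and
  percentile rescaling here match them at the contract level (what is
  detected on phantoms), not parameter-for-parameter.
* Greedy JI matching can differ from the optimal assignment in rare
  multi-overlap configurations; the optimal matcher is provided for
  cross-checks.
* The projected-footprint surface measure under-represents steep tumor
  flanks; use the voxel-face option when the geometry is not slab-like.
* Collagen "fiber count" is a connected-component proxy for a visual
  count and will merge crossing fibers.
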