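#' Assign detected cells to tumor regions
#'
#' Labels every cell `crater` if its centroid lies in, or within
#' `contact_dist` um of, a crater voxel; otherwise `tumor` under the same
#' rule; otherwise `outside`. Distances to the crater set, the tumor and
#' (when present) vessels are recorded from exact Euclidean distance
#' transforms, so a cell inside a region has distance 0 to it. The default
#' `contact_dist = 5` reflects the near/contacting convention (< 5 um away
#' from tumor); `contact_dist = 0` restricts to direct overlap.
#'
#' @param cells data.frame with centroid columns `z`, `y`, `x` (um).
#' @param masks a [region_mask_set()].
#' @param contact_dist contact distance in um.
#' @return `cells` with added `region`, `dist_to_crater`, `dist_to_tumor`,
#'   and `dist_to_vessel` (if vessels present).
#' @export
assign_cell_regions <- function(cells, masks, contact_dist = 5) {
  stopifnot(inherits(masks, "region_mask_set"))
  shp <- dim(masks$tumor)
  sp <- masks$spacing
  if (!any(masks$tumor != 0) && !any(masks$craters != 0))
    stop("empty masks: nothing to assign against")
  if (nrow(cells) == 0) {
    cells$region <- character(0)
    cells$dist_to_crater <- numeric(0)
    cells$dist_to_tumor <- numeric(0)
    if (!is.null(masks$vessels)) cells$dist_to_vessel <- numeric(0)
    return(cells)
  }
  vox <- function(coords) {
    # nearest voxel index per axis, clamped to the array
    m <- sapply(seq_along(shp), function(a)
      pmin(pmax(round(coords[[a]] / sp[a]) + 1L, 1L), shp[a]))
    matrix(m, ncol = length(shp))
  }
  cols <- if (length(shp) == 3L) c("z", "y", "x") else c("y", "x")
  vi <- vox(cells[cols])
  lookup <- function(mask) {
    if (is.null(mask) || !any(mask != 0)) return(rep(NA_real_, nrow(cells)))
    dm <- distance_map(mask, sp)
    dm[vi]
  }
  dcr <- lookup(masks$craters > 0)
  dtu <- lookup(masks$tumor)
  dve <- lookup(masks$vessels)
  region <- rep("outside", nrow(cells))
  region[!is.na(dtu) & dtu <= contact_dist] <- "tumor"
  region[!is.na(dcr) & dcr <= contact_dist] <- "crater"
  cells$region <- region
  cells$dist_to_crater <- dcr
  cells$dist_to_tumor <- dtu
  if (!is.null(masks$vessels)) cells$dist_to_vessel <- dve
  cells
}

#' Surface area of a mask
#'
#' Two estimators: `"projected"` (default) counts occupied (y, x) columns
#' of the z-projection times the pixel area — the natural measure for the
#' upper tumor surface of a slab-like tumor and the one used for coverage
#' and density denominators; `"voxel_face"` sums exposed voxel face areas
#' (spacing-aware), which overestimates oblique surfaces and is provided
#' for sensitivity checks.
#'
#' @param mask 0/1 array (2D masks are their own projection).
#' @param spacing per-axis voxel size (um).
#' @param method `"projected"` or `"voxel_face"`.
#' @return area in mm^2.
#' @export
surface_area <- function(mask, spacing, method = c("projected",
                                                   "voxel_face")) {
  method <- match.arg(method)
  d <- dim(mask)
  if (method == "projected") {
    px <- prod(spacing[(length(spacing) - 1):length(spacing)])
    proj <- if (length(d) == 3L) apply(mask != 0, c(2, 3), any) else mask != 0
    return(sum(proj) * px / 1e6)
  }
  m <- array(as.integer(mask != 0), d)
  total <- 0
  for (ax in seq_along(d)) {
    face <- prod(spacing[-ax])
    shifted <- array(0L, d)
    idx_to <- lapply(d, seq_len); idx_from <- idx_to
    idx_to[[ax]] <- seq_len(d[ax] - 1L); idx_from[[ax]] <- 2:d[ax]
    shifted <- do.call(`[<-`, c(list(shifted), idx_to,
      list(do.call(`[`, c(list(m), idx_from)))))
    total <- total + sum(m != shifted) * face
    # faces at the two array borders
    first <- do.call(`[`, c(list(m), replace(lapply(d, seq_len), ax,
                                             list(1L))))
    last <- do.call(`[`, c(list(m), replace(lapply(d, seq_len), ax,
                                            list(d[ax]))))
    total <- total + (sum(first != 0) + sum(last != 0)) * face
  }
  total / 1e6
}

#' Region-conditioned cell densities and affinity ratio
#'
#' Density = region-assigned cell count / region surface area (mm^2). The
#' affinity ratio is `density_crater / density_tumor` (reported `NA` when
#' the tumor density is zero or undefined).
#'
#' @param cells data.frame with a `region` column
#'   (see [assign_cell_regions()]).
#' @param masks a [region_mask_set()].
#' @param area_method passed to [surface_area()].
#' @return list of class `region_stats_report`: areas (mm^2), densities
#'   (cells/mm^2), `affinity_ratio`, counts.
#' @export
region_densities <- function(cells, masks, area_method = "projected") {
  a_cr <- if (any(masks$craters != 0))
    surface_area(masks$craters > 0, masks$spacing, area_method) else 0
  a_tu_total <- surface_area(masks$tumor != 0 | masks$craters > 0,
                             masks$spacing, area_method)
  a_tu <- a_tu_total - a_cr
  n_cr <- sum(cells$region == "crater")
  n_tu <- sum(cells$region == "tumor")
  d_cr <- if (a_cr > 0) n_cr / a_cr else {
    if (n_cr > 0) warning("crater cells present but crater area is zero")
    NA_real_
  }
  d_tu <- if (a_tu > 0) n_tu / a_tu else NA_real_
  aff <- if (!is.na(d_cr) && !is.na(d_tu) && d_tu > 0) d_cr / d_tu
         else NA_real_
  structure(list(crater_area_mm2 = a_cr, tumor_area_mm2 = a_tu,
                 n_crater = n_cr, n_tumor = n_tu,
                 n_outside = sum(cells$region == "outside"),
                 density_crater = d_cr, density_tumor = d_tu,
                 affinity_ratio = aff, area_method = area_method),
            class = "region_stats_report")
}

#' CRATER surface coverage and diameter distribution
#'
#' Coverage = 100 x projected crater footprint area / projected footprint
#' of tumor-plus-craters (the denominator includes the crater area itself;
#' pass `include_crater_area = FALSE` for the alternative convention).
#' Per-crater diameter is the equivalent-circle diameter of the crater's
#' surface-projected footprint, in um.
#'
#' @param masks a [region_mask_set()].
#' @param include_crater_area include crater area in the denominator.
#' @return list with `coverage_pct` and `diameters_um` (one per label).
#' @export
coverage_and_sizes <- function(masks, include_crater_area = TRUE) {
  sp <- masks$spacing
  d <- dim(masks$craters)
  px <- if (length(d) == 3L) sp[2] * sp[3] else sp[1] * sp[2]
  proj_lab <- if (length(d) == 3L)
    apply(masks$craters, c(2, 3), max) else masks$craters
  proj_tum <- if (length(d) == 3L)
    apply(masks$tumor != 0, c(2, 3), any) else masks$tumor != 0
  labels <- sort(setdiff(unique(as.vector(proj_lab)), 0L))
  areas <- vapply(labels, function(l) sum(proj_lab == l) * px, 0)
  a_cr <- sum(proj_lab > 0) * px
  denom <- if (include_crater_area) sum(proj_tum | proj_lab > 0) * px
           else sum(proj_tum & !(proj_lab > 0)) * px + 0
  coverage <- if (denom > 0) 100 * a_cr / denom else 0
  list(coverage_pct = unname(coverage),
       diameters_um = if (length(areas)) 2 * sqrt(areas / pi) else numeric(0),
       crater_area_um2 = a_cr, total_area_um2 = denom)
}

#' Histogram of object distances from a reference mask
#'
#' Distances are taken from the exact Euclidean distance transform of the
#' reference mask at each object's nearest voxel; objects inside the
#' reference fall in the first bin. Objects beyond the last edge are
#' counted in an overflow bin.
#'
#' @param objects data.frame of centroids (`z`, `y`, `x` or `y`, `x`, um).
#' @param reference 0/1 mask.
#' @param spacing per-axis voxel size (um).
#' @param bins increasing bin edges (um), starting at 0.
#' @return data.frame with `lower`, `upper` (um; last row `Inf`) and
#'   `count`.
#' @export
distance_profile <- function(objects, reference, spacing,
                             bins = c(0, 10, 25, 50, 100)) {
  if (!any(reference != 0)) stop("empty reference mask")
  shp <- dim(reference)
  dm <- distance_map(reference, spacing)
  cols <- if (length(shp) == 3L) c("z", "y", "x") else c("y", "x")
  vi <- sapply(seq_along(shp), function(a)
    pmin(pmax(round(objects[[cols[a]]] / spacing[a]) + 1L, 1L), shp[a]))
  dd <- dm[matrix(vi, ncol = length(shp))]
  edges <- c(bins, Inf)
  cts <- vapply(seq_len(length(edges) - 1L), function(i)
    sum(dd >= edges[i] & dd < edges[i + 1L]), 0L)
  data.frame(lower = edges[-length(edges)], upper = edges[-1], count = cts)
}

#' Fold change of 2D tumor area
#'
#' @param area_t0,area_t1 areas (mm^2) before and after treatment; must be
#'   positive.
#' @return `area_t1 / area_t0`.
#' @export
tumor_area_foldchange <- function(area_t0, area_t1) {
  if (any(c(area_t0, area_t1) <= 0)) stop("areas must be positive")
  area_t1 / area_t0
}

#' Two-group tests used throughout the analyses
#'
#' Two-sided Mann-Whitney U (exact for groups of up to 8 without ties,
#' normal approximation with tie correction otherwise), unpaired Welch t,
#' or paired t. All-tied MWU input returns p = 1 with a warning; a t test
#' on exactly separated zero-variance groups is reported as statistic
#' `Inf` with p = 0 and `degenerate = TRUE`.
#'
#' @param sample_a,sample_b numeric vectors (paired t requires equal
#'   length).
#' @param kind `"mwu"`, `"t_unpaired"` or `"t_paired"`.
#' @return list with `statistic`, `p`, `kind`, `exact` (MWU branch used),
#'   `degenerate`.
#' @export
group_test <- function(sample_a, sample_b,
                       kind = c("mwu", "t_unpaired", "t_paired")) {
  kind <- match.arg(kind)
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("need at least 2 observations per group")
  if (kind == "mwu") {
    ties <- any(duplicated(c(sample_a, sample_b)))
    if (length(unique(c(sample_a, sample_b))) == 1L) {
      warning("all observations tied; p = 1")
      return(list(statistic = length(sample_a) * length(sample_b) / 2,
                  p = 1, kind = kind, exact = FALSE, degenerate = TRUE))
    }
    use_exact <- !ties && length(sample_a) <= 8 && length(sample_b) <= 8
    wt <- suppressWarnings(wilcox.test(sample_a, sample_b,
                                       exact = use_exact, correct = TRUE,
                                       alternative = "two.sided"))
    return(list(statistic = unname(wt$statistic), p = wt$p.value,
                kind = kind, exact = use_exact, degenerate = FALSE))
  }
  paired <- kind == "t_paired"
  if (paired && length(sample_a) != length(sample_b))
    stop("paired test requires equal-length samples")
  degenerate <- if (paired) sd(sample_a - sample_b) == 0
                else sd(sample_a) == 0 && sd(sample_b) == 0
  if (degenerate) {
    same <- if (paired) all(sample_a == sample_b)
            else mean(sample_a) == mean(sample_b)
    return(list(statistic = if (same) 0 else Inf, p = if (same) 1 else 0,
                kind = kind, exact = FALSE, degenerate = TRUE))
  }
  tt <- t.test(sample_a, sample_b, paired = paired,
               alternative = "two.sided")
  list(statistic = unname(tt$statistic), p = tt$p.value, kind = kind,
       exact = FALSE, degenerate = FALSE)
}
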