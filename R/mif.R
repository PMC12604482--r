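#' Parameters for human mIF quantification
#'
#' @param norm_percentile channel normalization percentile (the published
#'   pipeline uses the 99th).
#' @param bg_radius rolling-ball background radius in pixels.
#' @param crater_size_range accepted CRATER equivalent-diameter range (um).
#' @param max_collagen_fibers maximum collagen fibers inside a CRATER
#'   ("one or two collagen fibers, but not more").
#' @param nuclear_density_frac a candidate passes the low-nuclear-density
#'   rule when its nuclei/um^2 is below this fraction of the perivascular
#'   nuclear density.
#' @param boundary_smoothing contour smoothing window (um) for boundary
#'   length measurement.
#' @param margin_width tumor margin band width (um).
#' @param hole_area_range area range (um^2) for a tumor hole to qualify as
#'   perivascular.
#' @param cd31_min_frac minimum CD31+/CD105+ pixel fraction inside a hole
#'   for the perivascular call.
#' @param positive_threshold marker positivity threshold on normalized
#'   intensities.
#' @return parameter list of class `mif_params`.
#' @export
mif_params <- function(norm_percentile = 99, bg_radius = 50L,
                       crater_size_range = c(20, 50),
                       max_collagen_fibers = 2L,
                       nuclear_density_frac = 0.5,
                       boundary_smoothing = 3,
                       margin_width = 50,
                       hole_area_range = c(2000, 50000),
                       cd31_min_frac = 0.002,
                       positive_threshold = 0.35) {
  stopifnot(norm_percentile > 0, norm_percentile <= 100,
            crater_size_range[1] > 0, diff(crater_size_range) > 0)
  structure(as.list(environment()), class = "mif_params")
}

#' Percentile-normalize channels and build the membrane composite
#'
#' Each listed membrane channel is divided by its `norm_percentile` value
#' (values above 1 clipped), then the membrane channels are summed into a
#' `membrane_sum` composite; the nuclear channel is normalized separately.
#' Idempotent up to clipping: normalizing an already-normalized channel is
#' a no-op within float tolerance.
#'
#' @param img multichannel 2D [calibrated_image()].
#' @param membrane_channels channel names to normalize and sum.
#' @param nuclear_channel nuclear channel name.
#' @param params an [mif_params()].
#' @return [calibrated_image()] with channels: each normalized input
#'   channel, `membrane_sum`, and the normalized nuclear channel.
#' @export
preprocess_channels <- function(img, membrane_channels, nuclear_channel,
                                params = mif_params()) {
  q <- params$norm_percentile / 100
  norm1 <- function(name) {
    ch <- get_channel(img, name)
    p <- quantile(ch, q)
    if (p <= 0) stop("channel '", name, "' has zero ",
                     params$norm_percentile, "th percentile")
    pmin(ch / p, 1)
  }
  normd <- lapply(membrane_channels, norm1)
  comp <- Reduce(`+`, normd)
  nuc <- norm1(nuclear_channel)
  arr <- array(0, c(dim(comp), length(normd) + 2L))
  for (i in seq_along(normd)) arr[, , i] <- normd[[i]]
  arr[, , length(normd) + 1L] <- comp
  arr[, , length(normd) + 2L] <- nuc
  calibrated_image(arr, img$spacing,
                   channels = c(membrane_channels, "membrane_sum",
                                nuclear_channel),
                   axes = "yxc")
}

#' Rolling-ball background subtraction
#'
#' Background estimated by grayscale morphological opening with a flat disc
#' of the given radius, then subtracted; the result is non-negative and
#' everywhere at most the input. A constant image maps to zero; structures
#' narrower than the disc are preserved.
#'
#' @param channel 2D numeric matrix.
#' @param radius ball radius in pixels.
#' @return background-subtracted matrix.
#' @export
subtract_background <- function(channel, radius = 50L) {
  if (2L * radius + 1L >= min(dim(channel)))
    stop("rolling-ball radius (", radius,
         " px) too large for image of size ",
         paste(dim(channel), collapse = "x"))
  rng <- range(channel)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  v <- (channel - rng[1]) / scale
  bg <- EBImage::opening(EBImage::Image(v),
                         EBImage::makeBrush(2L * as.integer(radius) + 1L,
                                            "disc"))
  out <- (v - as.numeric(bg)) * scale
  array(pmax(out, 0), dim(channel))
}

#' Per-cell mean channel intensities and centroids
#'
#' @param img multichannel 2D [calibrated_image()].
#' @param cell_mask integer cell label mask aligned to `img`.
#' @return data.frame: `id`, centroid `x`, `y` (um), `area_um2`, one mean
#'   column per channel.
#' @export
extract_cell_features <- function(img, cell_mask) {
  labs <- sort(setdiff(unique(as.vector(cell_mask)), 0L))
  if (!length(labs)) stop("empty cell mask")
  idx <- which(cell_mask > 0)
  l <- factor(cell_mask[idx], levels = labs)
  co <- arrayInd(idx, dim(cell_mask))
  sp <- img$spacing
  out <- data.frame(id = labs,
                    y = as.vector(tapply((co[, 1] - 1) * sp[1], l, mean)),
                    x = as.vector(tapply((co[, 2] - 1) * sp[2], l, mean)),
                    area_um2 = as.vector(table(l)) * prod(sp))
  for (ch in img$channels) {
    v <- get_channel(img, ch)
    out[[ch]] <- as.vector(tapply(v[idx], l, mean))
  }
  out
}

#' Default marker gating table
#'
#' Threshold gating on mean marker intensities replacing the published
#' cluster-then-curate step with a reproducible rule set. Priority order
#' resolves multi-gate cells: Treg (CD4+FOXP3+) before CD4 T, DC
#' (CD163+CD11c+) before single-marker calls.
#'
#' @return data.frame with `type`, `markers` (list of required-positive
#'   channels), in priority order.
#' @export
default_gates <- function() {
  data.frame(type = c("Treg", "DC", "CD8T", "CD4T", "tumor"),
             markers = I(list(c("CD4", "FOXP3"), c("CD163", "CD11c"),
                              "CD8a", "CD4", c("SOX10"))))
}

#' Assign cell types by threshold gating (or adopt provided labels)
#'
#' @param cells feature table from [extract_cell_features()].
#' @param gates gating table as in [default_gates()]; first matching gate
#'   in priority order wins; cells matching several exclusive gates are
#'   flagged `multi_gate`.
#' @param labels optional externally provided type labels (passthrough).
#' @param params an [mif_params()] (positivity threshold).
#' @return `cells` with `cell_type` (and `multi_gate`) columns.
#' @export
classify_cells <- function(cells, gates = default_gates(), labels = NULL,
                           params = mif_params()) {
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(cells))
    cells$cell_type <- labels
    return(cells)
  }
  thr <- params$positive_threshold
  missing <- setdiff(unique(unlist(gates$markers)), names(cells))
  if (length(missing))
    stop("gating table references absent channels: ",
         paste(missing, collapse = ", "))
  hit <- sapply(seq_len(nrow(gates)), function(g)
    Reduce(`&`, lapply(gates$markers[[g]], function(m) cells[[m]] > thr)))
  hit <- matrix(hit, nrow = nrow(cells))
  first <- apply(hit, 1, function(r) if (any(r)) which(r)[1] else NA)
  cells$cell_type <- ifelse(is.na(first), "other", gates$type[first])
  cells$multi_gate <- rowSums(hit) > 1
  cells
}

# Sub-pixel contour length of a single region: longest outer contour from
# EBImage::ocontour, smoothed with a circular moving average before summing
# segment lengths (digital contours overestimate length without smoothing).
contour_length_um <- function(mask, spacing, smooth_um = 5) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) return(0)
  total <- 0
  for (ct in oc) {
    pts <- cbind(ct[, 1] * spacing[1], ct[, 2] * spacing[2])
    n <- nrow(pts)
    if (n < 4) next
    w <- max(1L, round(smooth_um / mean(spacing)))
    if (w > 1 && n > 2 * w) {
      pad <- rbind(tail(pts, w), pts, head(pts, w))
      cs <- apply(pad, 2, cumsum)
      pts <- (cs[(2 * w + 1):(n + 2 * w), ] - cs[1:n, ]) / (2 * w)
    }
    seg <- sqrt(rowSums((pts - pts[c(2:n, 1), ])^2))
    total <- total + sum(seg)
  }
  total
}

#' Segment tumor, margin and perivascular areas on an mIF image
#'
#' Otsu thresholding of the (smoothed) tumor channel, morphological closing
#' to fill small holes and opening to drop small fragments; the margin is
#' the band within `margin_width` um outside the tumor; enclosed
#' segmentation holes are filtered by area and CD31/CD105 content into
#' perivascular areas (PVAs), and each PVA's boundary contour — the
#' perivascular-melanocytic boundary, PMB — is measured in cm on the
#' smoothed sub-pixel contour.
#'
#' @param img multichannel 2D [calibrated_image()].
#' @param tumor_channel,vessel_channel channel names.
#' @param params an [mif_params()].
#' @param close_radius,open_radius morphology radii (um).
#' @param sigma pre-threshold smoothing (um).
#' @return list: `tumor`, `margin`, `pva` (instance labels), `holes`
#'   (per-hole table with `perivascular` flag and `pmb_cm`),
#'   `pmb_total_cm`, `outer_boundary_cm`.
#' @export
segment_tumor_regions <- function(img, tumor_channel = "S100",
                                  vessel_channel = "CD31",
                                  params = mif_params(),
                                  close_radius = 6, open_radius = 4,
                                  sigma = 1.5) {
  sp <- img$spacing
  ch <- get_channel(img, tumor_channel)
  sm <- gaussian_smooth(ch, sigma, sp)
  mask <- array(as.integer(sm > otsu_threshold(sm)), dim(ch))
  px <- max(1L, round(close_radius / mean(sp)))
  brush <- EBImage::makeBrush(2L * px + 1L, "disc")
  m <- EBImage::closing(EBImage::Image(mask * 1), brush)
  pxo <- max(1L, round(open_radius / mean(sp)))
  m <- EBImage::opening(m, EBImage::makeBrush(2L * pxo + 1L, "disc"))
  tumor <- array(as.integer(as.numeric(m) > 0.5), dim(ch))
  if (!any(tumor != 0)) stop("empty tumor segmentation")
  dm <- distance_map(tumor, sp)
  margin <- array(as.integer(dm > 0 & dm <= params$margin_width), dim(ch))
  # enclosed holes: filled minus tumor
  filled <- fill_holes(tumor)
  holes_mask <- array(as.integer(filled != 0 & tumor == 0), dim(ch))
  hl <- label_components(holes_mask)
  ves <- get_channel(img, vessel_channel)
  # absolute floor alongside Otsu: a channel holding only noise must not
  # produce "positive" pixels
  ves_pos <- ves > max(otsu_threshold(ves), params$positive_threshold)
  labs <- sort(setdiff(unique(as.vector(hl)), 0L))
  holes <- data.frame(label = labs,
                      area_um2 = NA_real_, cd31_frac = NA_real_,
                      perivascular = FALSE, pmb_cm = 0)
  pva <- array(0L, dim(ch))
  for (i in seq_along(labs)) {
    sel <- hl == labs[i]
    holes$area_um2[i] <- sum(sel) * prod(sp)
    holes$cd31_frac[i] <- mean(ves_pos[sel])
    holes$perivascular[i] <-
      holes$area_um2[i] >= params$hole_area_range[1] &&
      holes$area_um2[i] <= params$hole_area_range[2] &&
      holes$cd31_frac[i] >= params$cd31_min_frac
    if (holes$perivascular[i]) {
      pva[sel] <- labs[i]
      holes$pmb_cm[i] <- contour_length_um(array(as.integer(sel), dim(ch)),
                                           sp,
                                           params$boundary_smoothing) / 1e4
    }
  }
  outer_cm <- contour_length_um(fill_holes(tumor), sp,
                                params$boundary_smoothing) / 1e4
  list(tumor = tumor, margin = margin, pva = pva, holes = holes,
       pmb_total_cm = sum(holes$pmb_cm[holes$perivascular]),
       outer_boundary_cm = outer_cm)
}

#' Compute rule features for CRATER candidate polygons
#'
#' For each candidate polygon: equivalent-circle diameter, whether it sits
#' on a stromal-melanocytic boundary (within `boundary_tol` um of the PMB
#' or the outer tumor margin), collagen fiber count (connected components
#' of the thresholded collagen channel inside the polygon), nuclear density
#' (cell-mask nuclei per um^2), and CD31/CD105 and aSMA overlap flags.
#'
#' @param candidates data.frame with a `polygon` list-column (n x 2
#'   matrices, x/y um).
#' @param regions result of [segment_tumor_regions()].
#' @param img preprocessed [calibrated_image()] with `COL`, `CD31`,
#'   `CD105`, `aSMA` channels (absent channels are treated as empty).
#' @param cell_mask integer cell label mask (nuclei).
#' @param params an [mif_params()].
#' @param boundary_tol distance tolerance (um) for the location rule.
#' @return `candidates` with feature columns added.
#' @export
crater_candidate_features <- function(candidates, regions, img, cell_mask,
                                      params = mif_params(),
                                      boundary_tol = 10) {
  sp <- img$spacing
  shp <- dim(regions$tumor)
  getch <- function(name) {
    if (name %in% img$channels) get_channel(img, name)
    else array(0, shp)
  }
  pos <- function(v) {
    if (diff(range(v)) == 0) return(v > Inf)
    v > max(otsu_threshold(v), params$positive_threshold)
  }
  col_pos <- pos(getch("COL"))
  ves_pos <- pos(getch("CD31")) | pos(getch("CD105"))
  asma_pos <- pos(getch("aSMA"))
  # distance to any stromal-melanoma interface: PMB (PVA boundary) or the
  # outer tumor boundary (margin inner edge)
  interface <- array(0L, shp)
  if (any(regions$pva != 0)) {
    pvad <- box_dilate(array(as.integer(regions$pva > 0), shp), 3L)
    interface[pvad != 0 & regions$pva == 0] <- 1L
  }
  tumd <- box_dilate(regions$tumor, 3L)
  interface[tumd != 0 & regions$tumor == 0] <- 1L
  dmi <- distance_map(interface, sp)
  nvac <- params$nuclear_density_frac
  candidates$equivalent_diameter <- NA_real_
  candidates$on_boundary <- NA
  candidates$collagen_fiber_count <- NA_integer_
  candidates$nuclear_density <- NA_real_
  candidates$vessel_overlap <- NA
  candidates$asma_overlap <- NA
  for (i in seq_len(nrow(candidates))) {
    ring <- candidates$polygon[[i]]
    ys <- (seq_len(shp[1]) - 1) * sp[1]
    xs <- (seq_len(shp[2]) - 1) * sp[2]
    yr <- range(ring[, 2]); xr <- range(ring[, 1])
    yi <- which(ys >= yr[1] - sp[1] & ys <= yr[2] + sp[1])
    xi <- which(xs >= xr[1] - sp[2] & xs <= xr[2] + sp[2])
    if (!length(yi) || !length(xi)) next
    gy <- rep(ys[yi], times = length(xi))
    gx <- rep(xs[xi], each = length(yi))
    ins <- points_in_polygon(gx, gy, ring)
    sel <- matrix(FALSE, shp[1], shp[2])
    sel[cbind(rep(yi, times = length(xi))[ins],
              rep(xi, each = length(yi))[ins])] <- TRUE
    area <- sum(sel) * prod(sp)
    candidates$equivalent_diameter[i] <- 2 * sqrt(area / pi)
    cyx <- c(mean(ring[, 2]), mean(ring[, 1]))
    vy <- pmin(pmax(round(cyx[1] / sp[1]) + 1L, 1L), shp[1])
    vx <- pmin(pmax(round(cyx[2] / sp[2]) + 1L, 1L), shp[2])
    candidates$on_boundary[i] <-
      dmi[vy, vx] <= candidates$equivalent_diameter[i] / 2 + boundary_tol
    fib <- array(as.integer(col_pos & sel), shp)
    candidates$collagen_fiber_count[i] <- max(label_components(fib))
    nuc <- unique(cell_mask[sel])
    candidates$nuclear_density[i] <- length(setdiff(nuc, 0L)) / area
    candidates$vessel_overlap[i] <- any(ves_pos & sel)
    candidates$asma_overlap[i] <- any(asma_pos & sel)
  }
  attr(candidates, "nuclear_density_frac") <- nvac
  candidates
}

#' Apply the CRATER identification rules to candidates
#'
#' Accepts a candidate iff it lies on a stromal-melanocytic boundary, its
#' equivalent diameter is within the size range (20-50 um), it contains at
#' most `max_collagen_fibers` collagen fibers, its nuclear density is below
#' `nuclear_density_frac` of the perivascular nuclear density, and it
#' contains neither CD31+/CD105+ vessel pixels nor aSMA+ pericytes. Every
#' rejection lists the failed rules.
#'
#' @param candidates feature table from [crater_candidate_features()].
#' @param perivascular_nuclear_density reference nuclei/um^2 of the
#'   perivascular stroma.
#' @param params an [mif_params()].
#' @return `candidates` with `accepted` and `failed_rules` columns.
#' @export
classify_crater_candidates <- function(candidates,
                                       perivascular_nuclear_density,
                                       params = mif_params()) {
  sz <- params$crater_size_range
  rules <- list(
    location = candidates$on_boundary,
    size = candidates$equivalent_diameter >= sz[1] &
           candidates$equivalent_diameter <= sz[2],
    collagen = candidates$collagen_fiber_count <= params$max_collagen_fibers,
    nuclear_density = candidates$nuclear_density <
      params$nuclear_density_frac * perivascular_nuclear_density,
    no_vessel = !candidates$vessel_overlap,
    no_asma = !candidates$asma_overlap)
  rl <- do.call(cbind, rules)
  candidates$accepted <- apply(rl, 1, all)
  candidates$failed_rules <- apply(rl, 1, function(r)
    paste(names(rules)[!r], collapse = ","))
  candidates
}

#' Assign cells to crater / border / tumor / outside with exclusion logic
#'
#' Cells overlapping a CRATER are crater cells; cells overlapping the
#' border (margin) region but not CRATERs are border cells; cells
#' overlapping the tumor segmentation without overlapping CRATERs or the
#' border are tumor cells; the rest are outside. Overlap means any pixel of
#' the cell's label falls in the region.
#'
#' @param cells feature table with `id` matching `cell_mask` labels.
#' @param cell_mask integer cell label mask.
#' @param crater_mask 0/1 (or instance) CRATER mask.
#' @param regions result of [segment_tumor_regions()].
#' @return `cells` with a `region` column.
#' @export
assign_cells_to_regions <- function(cells, cell_mask, crater_mask,
                                    regions) {
  overlap_ids <- function(region_mask) {
    unique(cell_mask[region_mask != 0 & cell_mask > 0])
  }
  in_cr <- overlap_ids(crater_mask)
  in_bd <- overlap_ids(regions$margin)
  in_tu <- overlap_ids(regions$tumor)
  region <- rep("outside", nrow(cells))
  region[cells$id %in% in_tu] <- "tumor"
  region[cells$id %in% in_bd] <- "border"
  region[cells$id %in% in_cr] <- "crater"
  cells$region <- region
  cells
}

#' Per-region, per-type cell densities (cells/mm^2)
#'
#' @param cells table with `region` and `cell_type`.
#' @param areas_mm2 named region areas in mm^2.
#' @return data.frame `region`, `cell_type`, `n`, `density_mm2`.
#' @export
region_type_densities <- function(cells, areas_mm2) {
  tab <- as.data.frame(table(region = cells$region,
                             cell_type = cells$cell_type),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab$density_mm2 <- ifelse(tab$region %in% names(areas_mm2) &
                              areas_mm2[tab$region] > 0,
                            tab$n / areas_mm2[tab$region], NA_real_)
  tab
}

#' CRATER linear density along the perivascular-melanocytic boundary
#'
#' Density = accepted CRATER count per linear cm of boundary; segments
#' flagged fibrotic are excluded from the length (areas of massive fibrosis
#' preclude a clear stromal-tumor border).
#'
#' @param n_craters accepted CRATER count.
#' @param boundary_cm per-segment boundary lengths (cm).
#' @param fibrotic logical flags per segment, excluded when TRUE.
#' @return craters per cm.
#' @export
crater_linear_density <- function(n_craters, boundary_cm,
                                  fibrotic = rep(FALSE,
                                                 length(boundary_cm))) {
  len <- sum(boundary_cm[!fibrotic])
  if (len <= 0) stop("zero usable boundary length")
  n_craters / len
}

#' Compare a marker's per-cell intensity between regions
#'
#' Mann-Whitney U on the marker intensity of cells inside vs outside
#' CRATERs (or any two-level grouping).
#'
#' @param cells feature table.
#' @param marker channel column name.
#' @param group logical vector (TRUE = in-CRATER) or a two-level factor.
#' @return list with the two distributions and the [group_test()] result.
#' @export
marker_region_comparison <- function(cells, marker, group) {
  g <- if (is.logical(group)) factor(group, c(FALSE, TRUE),
                                     c("elsewhere", "crater"))
       else factor(group)
  if (nlevels(g) != 2) stop("grouping must have exactly two levels")
  a <- cells[[marker]][g == levels(g)[2]]
  b <- cells[[marker]][g == levels(g)[1]]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 cells per group")
  list(group_levels = levels(g), in_group = a, out_group = b,
       test = group_test(a, b, "mwu"))
}
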