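#' Parameters for RNAscope 2D quantification
#'
#' @param neighbor_radius foci-filter radius (um); a focus is kept only if
#'   it has at least `min_neighbors` other foci within this radius.
#' @param min_neighbors minimum neighbor count (default: at least two other
#'   foci within 10 um).
#' @param kde_bandwidth Gaussian KDE bandwidth (um); about half a T-cell
#'   diameter so transcript clouds of one cell merge into one density peak.
#' @param edge_width tumor edge band width (um).
#' @param kde_peak_min minimum KDE density (foci/um^2) for a peak to be
#'   called a cell.
#' @return parameter list of class `rnascope_params`.
#' @export
rnascope_params <- function(neighbor_radius = 10, min_neighbors = 2L,
                            kde_bandwidth = 5, edge_width = 15,
                            kde_peak_min = 0.02) {
  stopifnot(neighbor_radius > 0, edge_width > 0, kde_bandwidth > 0)
  structure(list(neighbor_radius = neighbor_radius,
                 min_neighbors = as.integer(min_neighbors),
                 kde_bandwidth = kde_bandwidth, edge_width = edge_width,
                 kde_peak_min = kde_peak_min),
            class = "rnascope_params")
}

#' Neighbor-count filtering of detected foci
#'
#' Keeps focus i iff at least `min_neighbors` other foci lie within
#' `neighbor_radius` um (exact pairwise distances; the DBSCAN-style rule
#' that suppresses non-specific isolated signal).
#'
#' @param foci data.frame with `x`, `y` in um.
#' @param params an [rnascope_params()].
#' @return the retained subset of `foci` (attribute `kept` holds the
#'   logical keep vector over the input).
#' @export
filter_foci <- function(foci, params = rnascope_params()) {
  n <- nrow(foci)
  if (n == 0) {
    attr(foci, "kept") <- logical(0)
    return(foci)
  }
  dm <- as.matrix(dist(foci[, c("x", "y")]))
  nb <- rowSums(dm <= params$neighbor_radius) - 1L
  keep <- unname(nb >= params$min_neighbors)
  out <- foci[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept") <- keep
  out
}

#' Gaussian kernel density map of foci on a pixel grid
#'
#' Evaluates an isotropic Gaussian KDE (bandwidth in um) at every pixel
#' center, in units of foci per um^2, so the map integral over the image
#' (density x pixel area) equals the number of foci up to the mass lying
#' outside the field. Kernels are truncated at 5 sigma.
#'
#' @param foci data.frame with `x`, `y` in um (at least one focus).
#' @param shape (ny, nx) output grid.
#' @param spacing (y, x) pixel size (um).
#' @param params an [rnascope_params()].
#' @return a 2D [calibrated_image()] of densities.
#' @export
kde_density_map <- function(foci, shape, spacing = c(1, 1),
                            params = rnascope_params()) {
  if (nrow(foci) == 0) stop("KDE undefined for zero foci")
  h <- params$kde_bandwidth
  ny <- shape[1]; nx <- shape[2]
  map <- matrix(0, ny, nx)
  ys <- (seq_len(ny) - 1) * spacing[1]
  xs <- (seq_len(nx) - 1) * spacing[2]
  cut <- 5 * h
  for (i in seq_len(nrow(foci))) {
    yr <- which(ys >= foci$y[i] - cut & ys <= foci$y[i] + cut)
    xr <- which(xs >= foci$x[i] - cut & xs <= foci$x[i] + cut)
    if (!length(yr) || !length(xr)) next
    gy <- exp(-0.5 * ((ys[yr] - foci$y[i]) / h)^2)
    gx <- exp(-0.5 * ((xs[xr] - foci$x[i]) / h)^2)
    map[yr, xr] <- map[yr, xr] + outer(gy, gx) / (2 * pi * h^2)
  }
  calibrated_image(map, spacing, axes = "yx")
}

#' Call cells from a KDE density map
#'
#' Local maxima of the (already smooth) density map above
#' `kde_peak_min` become cell calls; plateau maxima are merged to their
#' centroid. Peaks closer than the bandwidth merge by construction of the
#' KDE (documented behavior for sub-resolution cell pairs).
#'
#' @param kde_map 2D [calibrated_image()] from [kde_density_map()].
#' @param params an [rnascope_params()].
#' @return data.frame with `id`, `x`, `y` (um), `peak_density`.
#' @export
call_cells_from_kde <- function(kde_map, params = rnascope_params()) {
  m <- kde_map$data
  sp <- kde_map$spacing
  mx <- cpp_local_max(as.numeric(m), dim(m), params$kde_peak_min)
  lab <- label_components(array(as.integer(mx), dim(m)))
  nlab <- max(lab)
  if (nlab == 0)
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      peak_density = numeric(0)))
  out <- data.frame(id = seq_len(nlab), x = NA_real_, y = NA_real_,
                    peak_density = NA_real_)
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    out$y[l] <- mean((idx[, 1] - 1) * sp[1])
    out$x[l] <- mean((idx[, 2] - 1) * sp[2])
    out$peak_density[l] <- max(m[lab == l])
  }
  out
}

#' Tumor mask and edge band on a projected 2D image
#'
#' Smoothing + Otsu + morphological closing (disc) of the tumor channel;
#' the edge band contains every pixel whose Euclidean distance to the tumor
#' lies in (0, `edge_width`] um (equivalently, dilation by `edge_width`
#' minus the tumor, computed on the exact distance transform).
#'
#' @param img 2D [calibrated_image()].
#' @param channel tumor channel name.
#' @param closing_radius gap-filling closing radius (um).
#' @param params an [rnascope_params()].
#' @param sigma pre-threshold smoothing (um).
#' @return list with `tumor` and `edge` 0/1 masks.
#' @export
segment_tumor_2d <- function(img, channel = NULL, closing_radius = 5,
                             params = rnascope_params(), sigma = 1) {
  ch <- get_channel(img, channel)
  if (diff(range(ch)) == 0) stop("no foreground: channel is constant")
  sm <- gaussian_smooth(ch, sigma, img$spacing)
  mask <- sm > otsu_threshold(sm)
  r_px <- max(1L, round(closing_radius / mean(img$spacing)))
  closed <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(2L * r_px + 1L, "disc"))
  tumor <- array(as.integer(closed > 0.5), dim(ch))
  if (!any(tumor != 0)) stop("empty tumor segmentation")
  dm <- distance_map(tumor, img$spacing)
  edge <- array(as.integer(dm > 0 & dm <= params$edge_width), dim(ch))
  list(tumor = tumor, edge = edge)
}

#' Associate ifng foci with cells and summarize per region
#'
#' Every focus is assigned to at most one cell — the nearest whose center
#' lies within `assoc_radius` um (ties broken toward the lower cell id).
#' Adds `foci_count` per cell and summarizes the percentage of cells with
#' at least one focus per region.
#'
#' @param cells data.frame with `id`, `x`, `y` and (optionally) `region`.
#' @param ifng_foci data.frame with `x`, `y` (um).
#' @param assoc_radius association radius (um); defaults to the KDE
#'   bandwidth-scale cell radius.
#' @return list with `cells` (plus `foci_count`) and `summary`
#'   (per-region percent of focus-positive cells).
#' @export
quantify_ifng <- function(cells, ifng_foci, assoc_radius = 7.5) {
  cells$foci_count <- 0L
  if (nrow(cells) && nrow(ifng_foci)) {
    for (f in seq_len(nrow(ifng_foci))) {
      dd <- sqrt((cells$x - ifng_foci$x[f])^2 +
                 (cells$y - ifng_foci$y[f])^2)
      j <- which(dd <= assoc_radius)
      if (length(j)) {
        j <- j[order(dd[j], cells$id[j])][1]
        cells$foci_count[j] <- cells$foci_count[j] + 1L
      }
    }
  }
  summary <- if ("region" %in% names(cells) && nrow(cells)) {
    ag <- aggregate(cells$foci_count >= 1,
                    by = list(region = cells$region),
                    FUN = function(v) 100 * mean(v))
    names(ag)[2] <- "pct_positive"
    ag
  } else data.frame(region = character(0), pct_positive = numeric(0))
  list(cells = cells, summary = summary)
}
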