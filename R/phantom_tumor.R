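#' Synthetic 3D tumor phantom with surface pockets (CRATERs)
#'
#' Generates a 3-channel 3D stack emulating confocal imaging of a zebrafish
#' melanoma: a slab tumor whose flat top face bears hemispherical pockets
#' carved into the surface (CRATER morphology), bright spherical CD8-like
#' cells placed in pockets, on the surface, embedded in the tumor or outside
#' it, optional tubular vessels running beneath the surface, and additive
#' Gaussian noise on a constant background. The accompanying truth manifest
#' is computed by direct voxel counting and analytic geometry on the planted
#' shapes, never by the analysis pipeline.
#'
#' Defaults emulate the study conditions: pocket diameters around 45-50 um
#' (zebrafish CRATERs measure ~50 um across) at a count giving ~12% surface
#' coverage on the default field, 10 um cells, z-spacing twice the lateral
#' spacing, and a 4:1 crater:tumor cell-density ratio (CD8 density is
#' several-fold higher in CRATERs than on the rest of the tumor surface).
#'
#' @param shape (z, y, x) voxel dimensions.
#' @param spacing (z, y, x) voxel size in um.
#' @param pocket_count number of pockets carved into the top face.
#' @param pocket_diameter `c(mean, sd)` um of a truncated-normal diameter
#'   draw, or a single number for fixed diameters.
#' @param pocket_depth pocket depth in um; default half the diameter
#'   (hemispherical cap).
#' @param n_cells_tumor cells planted on the tumor surface outside pockets.
#' @param density_ratio planted crater:tumor surface cell-density ratio;
#'   the in-pocket cell count is derived from it and the realized areas.
#' @param n_cells_embedded cells at least two radii beneath the surface.
#' @param n_cells_outside cells detached from the tumor (> 15 um above).
#' @param cell_radius cell radius (um).
#' @param n_bright_cells bright punctae in the tumor channel (to be
#'   excluded before tumor segmentation), radius `bright_radius` um.
#' @param bright_radius radius of bright punctae (um).
#' @param vessel_count,vessel_radius,vessel_depth tubes along x beneath the
#'   top face: count, radius (um), depth of centerline below surface (um).
#' @param background,tumor_amp,cell_amp,vessel_amp,noise_sd intensity model.
#' @param min_cell_separation minimum distance between planted cell
#'   centers (um).
#' @param max_attempts resampling attempts for non-overlapping placement
#'   before erroring.
#' @param seed integer; the phantom is a pure function of arguments + seed.
#' @return list with `image` (a [calibrated_image()], channels
#'   `tumor`, `cells`, `vessels`), `truth` manifest (pockets, cells,
#'   vessels, true masks, coverage fraction, areas, planted density ratio).
#' @export
make_tumor_phantom <- function(shape = c(48, 220, 220),
                               spacing = c(2, 1, 1),
                               pocket_count = 3,
                               pocket_diameter = c(50, 8),
                               pocket_depth = NULL,
                               n_cells_tumor = 40,
                               density_ratio = 4,
                               n_cells_embedded = 8,
                               n_cells_outside = 4,
                               cell_radius = 5,
                               n_bright_cells = 0,
                               bright_radius = 3,
                               vessel_count = 0,
                               vessel_radius = 6,
                               vessel_depth = 25,
                               background = 10, tumor_amp = 100,
                               cell_amp = 150, vessel_amp = 120,
                               noise_sd = 2,
                               min_cell_separation = 14,
                               max_attempts = 2000,
                               seed = 1) {
  with_seed(seed, {
    shape <- as.integer(shape); names(shape) <- c("z", "y", "x")
    names(spacing) <- c("z", "y", "x")
    zc <- (seq_len(shape[1]) - 1) * spacing[1]
    yc <- (seq_len(shape[2]) - 1) * spacing[2]
    xc <- (seq_len(shape[3]) - 1) * spacing[3]
    z_top <- zc[round(0.6 * shape[1])]          # top-face z coordinate (um)
    tumor0 <- array(0L, shape)
    tumor0[zc <= z_top, , ] <- 1L

    # -- pockets: hemispherical caps carved downward from the top face
    if (length(pocket_diameter) == 1L) pocket_diameter <- c(pocket_diameter, 0)
    lat_extent <- min((shape[2] - 1) * spacing[2], (shape[3] - 1) * spacing[3])
    centers <- matrix(numeric(0), 0, 2)
    diams <- numeric(0)
    att <- 0
    while (nrow(centers) < pocket_count) {
      att <- att + 1
      if (att > max_attempts)
        stop("could not place ", pocket_count,
             " non-overlapping pockets in ", max_attempts, " attempts")
      d0 <- rnorm(1, pocket_diameter[1], pocket_diameter[2])
      if (d0 <= spacing[3] * 4 || d0 >= lat_extent) next
      r0 <- d0 / 2
      cy <- runif(1, r0 + 5, max(yc) - r0 - 5)
      cx <- runif(1, r0 + 5, max(xc) - r0 - 5)
      if (nrow(centers)) {
        sep <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        if (any(sep < (diams / 2 + r0) * 1.15)) next
      }
      centers <- rbind(centers, c(cy, cx))
      diams <- c(diams, d0)
    }
    carved <- array(0L, shape)
    pocket_vox <- integer(length(diams))
    depth <- pocket_depth
    for (i in seq_along(diams)) {
      r0 <- diams[i] / 2
      dep <- if (is.null(depth)) r0 else depth
      # ellipsoidal cap: lateral radius r0, vertical semi-axis dep
      dz <- (zc - z_top) / dep
      dy <- (yc - centers[i, 1]) / r0
      dx <- (xc - centers[i, 2]) / r0
      sph <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`) <= 1
      sel <- sph & tumor0 == 1L
      carved[sel] <- i
      pocket_vox[i] <- sum(sel)
    }
    tumor <- tumor0
    tumor[carved > 0] <- 0L

    # -- true coverage by direct column counting on the carved mask
    carved_cols <- apply(carved > 0, c(2, 3), any)
    foot_cols <- apply(tumor0 > 0, c(2, 3), any)
    coverage <- sum(carved_cols) / sum(foot_cols | carved_cols)
    px_area <- spacing[2] * spacing[3]
    area_crater_um2 <- sum(carved_cols) * px_area
    area_tumor_um2 <- sum(foot_cols & !carved_cols) * px_area

    # -- cells
    n_cells_crater <- if (pocket_count > 0 && area_crater_um2 > 0)
      max(1L, round(density_ratio * n_cells_tumor *
                    area_crater_um2 / area_tumor_um2)) else 0L
    cells <- matrix(numeric(0), 0, 3,
                    dimnames = list(NULL, c("z", "y", "x")))
    region <- character(0)
    place <- function(gen, n, reg) {
      att <- 0
      while (n > 0) {
        att <- att + 1
        if (att > max_attempts)
          stop("could not place non-overlapping cells (region ", reg, ")")
        p <- gen()
        if (is.null(p) || anyNA(p)) next
        if (nrow(cells)) {
          if (min(sqrt(rowSums((cells -
              matrix(p, nrow(cells), 3, byrow = TRUE))^2))) <
              min_cell_separation) next
        }
        cells <<- rbind(cells, p)
        region <<- c(region, reg)
        n <- n - 1
      }
    }
    carved_idx <- which(carved > 0)
    if (n_cells_crater > 0 && length(carved_idx))
      place(function() {
        i <- sample(carved_idx, 1)
        co <- arrayInd(i, shape)
        c(zc[co[1]], yc[co[2]], xc[co[3]])
      }, n_cells_crater, "crater")
    # tumor-surface cells stay region_buffer um clear of carved columns so
    # their truth label is unambiguous under the 5 um contact convention
    region_buffer <- 8
    col_dist <- if (any(carved_cols))
      distance_map(carved_cols * 1L, spacing[2:3]) else
      array(Inf, dim(carved_cols))
    free_cols <- which(foot_cols & !carved_cols & col_dist > region_buffer,
                       arr.ind = TRUE)
    mb <- min(8L, min(shape[2:3]) %/% 4L)
    free_cols <- free_cols[free_cols[, 1] > mb & free_cols[, 2] > mb &
                           free_cols[, 1] < shape[2] - mb &
                           free_cols[, 2] < shape[3] - mb, , drop = FALSE]
    if (n_cells_tumor > 0 && nrow(free_cols) == 0)
      stop("no tumor-surface columns left for cell placement; ",
           "field too small for the requested pockets")
    place(function() {
      rc <- free_cols[sample(nrow(free_cols), 1), , drop = TRUE]
      c(z_top + 2, yc[rc[1]], xc[rc[2]])
    }, n_cells_tumor, "tumor")
    if (n_cells_embedded > 0)
      place(function() {
        rc <- free_cols[sample(nrow(free_cols), 1), ]
        zmax <- z_top - 2 * cell_radius
        if (zmax <= cell_radius) return(NULL)
        c(runif(1, cell_radius, zmax), yc[rc[1]], xc[rc[2]])
      }, n_cells_embedded, "embedded")
    if (n_cells_outside > 0)
      place(function() {
        zmin <- z_top + 16
        if (zmin >= max(zc) - 2) return(NULL)
        c(runif(1, zmin, max(zc) - 2), runif(1, 8, max(yc) - 8),
          runif(1, 8, max(xc) - 8))
      }, n_cells_outside, "outside")

    # -- vessels: tubes along x at vessel_depth below the top face
    vessel_mask <- array(0L, shape)
    vcl <- data.frame(z = numeric(0), y = numeric(0))
    for (v in seq_len(vessel_count)) {
      vy <- runif(1, 15, max(yc) - 15)
      vz <- z_top - vessel_depth
      if (vz < 0) vz <- 0
      dz2 <- ((zc - vz) * 1)^2
      dy2 <- ((yc - vy) * 1)^2
      tube2d <- outer(dz2, dy2, `+`) <= vessel_radius^2
      vessel_mask[rep(tube2d, shape[3])] <- 1L
      vcl <- rbind(vcl, data.frame(z = vz, y = vy))
    }

    # -- intensity channels
    paint_spheres <- function(pts, radius, amp) {
      ch <- array(0, shape)
      for (i in seq_len(nrow(pts))) {
        dz <- (zc - pts[i, 1])^2
        dy <- (yc - pts[i, 2])^2
        dx <- (xc - pts[i, 3])^2
        ch[outer(outer(dz, dy, `+`), dx, `+`) <= radius^2] <- amp
      }
      ch
    }
    ch_tumor <- background + tumor_amp * tumor +
      array(rnorm(prod(shape), 0, noise_sd), shape)
    bright <- matrix(numeric(0), 0, 3)
    if (n_bright_cells > 0) {
      bz <- runif(n_bright_cells, 5, z_top - 5)
      by <- runif(n_bright_cells, 15, max(yc) - 15)
      bx <- runif(n_bright_cells, 15, max(xc) - 15)
      bright <- cbind(z = bz, y = by, x = bx)
      ch_tumor <- ch_tumor + paint_spheres(bright, bright_radius,
                                           4 * tumor_amp)
    }
    cellpts <- cells
    ch_cells <- background +
      (if (nrow(cellpts)) paint_spheres(cellpts, cell_radius, cell_amp)
       else 0) + array(rnorm(prod(shape), 0, noise_sd), shape)
    ch_ves <- background + vessel_amp * vessel_mask +
      array(rnorm(prod(shape), 0, noise_sd), shape)

    img <- calibrated_image(
      array(c(ch_tumor, ch_cells, ch_ves), c(shape, 3L)),
      spacing, channels = c("tumor", "cells", "vessels"), axes = "zyxc")

    truth <- list(
      z_top_um = z_top,
      pockets = data.frame(y = centers[, 1], x = centers[, 2],
                           z = rep(z_top, length(diams)),
                           diameter_um = diams, voxels = pocket_vox),
      coverage_fraction = coverage,
      area_crater_um2 = area_crater_um2,
      area_tumor_um2 = area_tumor_um2,
      planted_density_ratio =
        if (n_cells_crater > 0 && n_cells_tumor > 0)
          (n_cells_crater / area_crater_um2) /
          (n_cells_tumor / area_tumor_um2) else NA_real_,
      cells = if (nrow(cells))
        data.frame(cells, region = region) else
        data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                   region = character(0)),
      bright_cells = bright,
      vessel_centerlines = vcl,
      tumor_mask = tumor, crater_mask = carved,
      vessel_mask = vessel_mask, spacing = spacing)
    list(image = img, truth = truth)
  })
}
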