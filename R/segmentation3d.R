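#' Parameters for the 3D segmentation pipeline
#'
#' @param gaussian_sigma pre-threshold smoothing sigma (um).
#' @param closing_kernel closing structuring-element size, voxels (the
#'   black top-hat uses a cubic 40-voxel kernel by default).
#' @param opening_kernel clean-up opening size, voxels.
#' @param min_crater_volume minimum crater instance volume (voxels) kept
#'   after opening.
#' @param blob_min_sigma,blob_max_sigma cell blob scale range (um);
#'   defaults bracket T cells of ~10 um diameter.
#' @param blob_threshold blob detector response threshold (fraction of
#'   dynamic range).
#' @param bright_cell_percentile percentile used to rescale the channel
#'   before bright-cell blob detection.
#' @return a parameter list of class `seg3d_params`.
#' @export
seg3d_params <- function(gaussian_sigma = 1.5,
                         closing_kernel = 40L,
                         opening_kernel = 2L,
                         min_crater_volume = 27L,
                         blob_min_sigma = 3, blob_max_sigma = 8,
                         blob_threshold = 0.08,
                         bright_cell_percentile = 99) {
  if (!(closing_kernel > opening_kernel && opening_kernel >= 1))
    stop("require closing_kernel > opening_kernel >= 1")
  structure(list(gaussian_sigma = gaussian_sigma,
                 closing_kernel = as.integer(closing_kernel),
                 opening_kernel = as.integer(opening_kernel),
                 min_crater_volume = as.integer(min_crater_volume),
                 blob_min_sigma = blob_min_sigma,
                 blob_max_sigma = blob_max_sigma,
                 blob_threshold = blob_threshold,
                 bright_cell_percentile = bright_cell_percentile),
            class = "seg3d_params")
}

#' Segment the tumor mass in a 3D stack
#'
#' Gaussian noise reduction followed by Otsu thresholding of the tumor
#' channel; voxels of an optional exclusion mask (bright cells) are reset to
#' the channel's background level before thresholding. The largest connected
#' component is kept.
#'
#' @param img a 3D [calibrated_image()].
#' @param channel tumor channel name.
#' @param params a [seg3d_params()].
#' @param exclude optional 0/1 array of voxels to suppress.
#' @return integer 0/1 tumor mask.
#' @export
segment_tumor <- function(img, channel = "tumor", params = seg3d_params(),
                          exclude = NULL) {
  stopifnot(inherits(img, "calibrated_image"), n_spatial_axes(img) == 3L)
  ch <- get_channel(img, channel)
  if (diff(range(ch)) == 0) stop("no foreground: channel is constant")
  if (!is.null(exclude) && any(exclude != 0))
    ch[exclude != 0] <- quantile(ch, 0.2)
  sm <- gaussian_smooth(ch, params$gaussian_sigma, img$spacing)
  th <- otsu_threshold(sm)
  mask <- array(as.integer(sm > th), dim(ch))
  if (!any(mask != 0)) stop("no foreground after thresholding")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  array(as.integer(lab == which.max(sizes)), dim(ch))
}

#' Detect bright punctae to exclude from tumor segmentation
#'
#' Percentile-rescales the channel, then runs the multiscale blob detector
#' and paints each detection as a sphere of its estimated radius. The
#' returned mask marks voxels to remove before tumor segmentation; an empty
#' mask is legitimate. Border-truncated detections are retained and flagged
#' in the `blobs` attribute.
#'
#' @inheritParams segment_tumor
#' @param channel channel carrying the bright cells.
#' @return integer 0/1 array with attribute `blobs` (the detection table).
#' @export
exclude_bright_cells <- function(img, channel = "tumor",
                                 params = seg3d_params()) {
  ch <- get_channel(img, channel)
  # rescale by the bright percentile without clipping: punctae stand out
  # above 1 while bulk tumor signal sits near or below it
  p <- quantile(ch, params$bright_cell_percentile / 100)
  if (p <= 0) p <- max(ch)
  v <- ch / p
  dim(v) <- dim(ch)
  blobs <- detect_blobs(v, img$spacing,
                        min_sigma = params$blob_min_sigma / 2,
                        max_sigma = params$blob_max_sigma / 2,
                        threshold = 0.6, normalize = FALSE)
  mask <- array(0L, dim(ch))
  sp <- img$spacing
  zc <- (seq_len(dim(ch)[1]) - 1) * sp[1]
  yc <- (seq_len(dim(ch)[2]) - 1) * sp[2]
  xc <- (seq_len(dim(ch)[3]) - 1) * sp[3]
  for (i in seq_len(nrow(blobs))) {
    r <- blobs$radius_um[i]
    mask[outer(outer((zc - blobs$z[i])^2, (yc - blobs$y[i])^2, `+`),
               (xc - blobs$x[i])^2, `+`) <= r^2] <- 1L
  }
  attr(mask, "blobs") <- blobs
  mask
}

#' Segment CRATERs by 3D black top-hat of the tumor mask
#'
#' Morphological closing of the tumor mask with a cubic `closing_kernel`
#' structuring element (the volume is padded with background by the kernel
#' size first, so no phantom craters appear at image borders), subtraction
#' of the tumor, then a clean-up opening with `opening_kernel` to remove
#' residue from the mismatch between tumor morphology and the cubic kernel.
#' Connected components are labeled; instances below `min_crater_volume`
#' voxels are discarded; components touching the image border are reported
#' in the `border_labels` attribute.
#'
#' @param tumor integer 0/1 tumor mask (3D).
#' @param params a [seg3d_params()].
#' @return integer crater instance mask (0 background) with attribute
#'   `border_labels`.
#' @export
segment_craters <- function(tumor, params = seg3d_params()) {
  if (!any(tumor != 0)) stop("empty tumor mask")
  closed <- box_close(tumor, params$closing_kernel)
  th <- closed
  th[tumor != 0] <- 0L
  opened <- box_open(th, params$opening_kernel)
  lab <- label_components(opened)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < params$min_crater_volume)
    if (length(drop)) lab[lab %in% drop] <- 0L
    # relabel compactly, preserving raster order
    keep <- sort(setdiff(unique(as.vector(lab)), 0L))
    lab <- array(match(lab, keep, nomatch = 0L), dim(lab))
  }
  attr(lab, "border_labels") <- border_labels(lab)
  lab
}

#' Detect cells in a 3D stack
#'
#' Gaussian noise reduction followed by multiscale difference-of-Gaussian
#' blob detection on the cell channel. Cells closer than the blob scale
#' merge into a single detection (documented detector behavior).
#'
#' @inheritParams segment_tumor
#' @param channel cell channel name.
#' @return data.frame of detections (centroids in um, estimated radius).
#' @export
detect_cells <- function(img, channel = "cells", params = seg3d_params()) {
  ch <- get_channel(img, channel)
  detect_blobs(ch, img$spacing,
               min_sigma = params$blob_min_sigma,
               max_sigma = params$blob_max_sigma,
               threshold = params$blob_threshold)
}
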